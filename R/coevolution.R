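## Correlated-mutation (coevolution) scores over TM alignment columns.
##
## All scores are computed on the filtered alignment (TM columns only) and
## are symmetric in (i, j). Gap handling: MI/MIp/MIc/OMES use pairwise row
## deletion (a row counts for columns i,j only when both residues are
## standard amino acids); McBASC skips row pairs with any gap at i or j.
## No pseudocounts anywhere.

codes_matrix <- function(filtered) {
  matrix(aa_code(filtered$mat), nrow = nrow(filtered$mat))
}

## MI between two integer-coded columns (0 = gap), natural log, 0*log 0 := 0
.mi_codes <- function(a, b, warn_few = TRUE) {
  v <- a > 0L & b > 0L
  a <- a[v]; b <- b[v]
  n <- length(a)
  if (n < 2L) {
    if (warn_few) warn("fewer than 2 ungapped rows; MI set to 0")
    return(0)
  }
  jt <- tabulate((a - 1L) * 20L + b, nbins = 400L)
  pa <- tabulate(a, nbins = 20L) / n
  pb <- tabulate(b, nbins = 20L) / n
  idx <- which(jt > 0L)
  pj <- jt[idx] / n
  ai <- (idx - 1L) %/% 20L + 1L
  bi <- (idx - 1L) %% 20L + 1L
  sum(pj * log(pj / (pa[ai] * pb[bi])))
}

.omes_codes <- function(a, b, warn_few = TRUE) {
  v <- a > 0L & b > 0L
  a <- a[v]; b <- b[v]
  n <- length(a)
  if (n < 2L) {
    if (warn_few) warn("fewer than 2 ungapped rows; OMES set to 0")
    return(0)
  }
  nobs <- matrix(tabulate((a - 1L) * 20L + b, nbins = 400L),
                 nrow = 20L, byrow = TRUE)
  na <- tabulate(a, nbins = 20L)
  nb <- tabulate(b, nbins = 20L)
  nex <- outer(na, nb) / n
  occ <- nex > 0
  sum((nobs[occ] - nex[occ])^2) / n
}

## substitution-similarity vectors over all unordered row pairs, NA at gaps
.mcbasc_simvec <- function(col_codes, pairs_k, pairs_l, smat) {
  a <- col_codes[pairs_k]; b <- col_codes[pairs_l]
  out <- rep(NA_real_, length(a))
  v <- a > 0L & b > 0L
  out[v] <- smat[cbind(a[v], b[v])]
  out
}

.row_pairs <- function(n) {
  k <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  l <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  list(k = k, l = l)
}

full_mi_matrix <- function(codes) {
  p <- ncol(codes)
  m <- matrix(0, p, p)
  few <- FALSE
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      m[i, j] <- m[j, i] <- .mi_codes(codes[, i], codes[, j], warn_few = FALSE)
      if (sum(codes[, i] > 0L & codes[, j] > 0L) < 2L) few <- TRUE
    }
  }
  if (few) warn("some column pairs had fewer than 2 ungapped rows; MI set to 0")
  m
}

## column means excluding the diagonal, and the APC / additive corrections
.apc_terms <- function(mi_mat) {
  p <- ncol(mi_mat)
  colmean <- (colSums(mi_mat)) / (p - 1L)
  overall <- sum(mi_mat[upper.tri(mi_mat)]) / (p * (p - 1L) / 2L)
  list(colmean = colmean, overall = overall)
}

full_coev_matrix <- function(filtered, method,
                             mic_correction = c("additive", "apc"),
                             similarity = MCLACHLAN) {
  method <- match.arg(method, c("MI", "MIp", "MIc", "OMES", "McBASC"))
  mic_correction <- match.arg(mic_correction)
  codes <- codes_matrix(filtered)
  p <- ncol(codes)
  if (method %in% c("MI", "MIp", "MIc")) {
    mi <- full_mi_matrix(codes)
    if (method == "MI") { m <- mi }
    else {
      t <- .apc_terms(mi)
      if (t$overall == 0) {
        m <- matrix(0, p, p)
      } else if (method == "MIp" || mic_correction == "apc") {
        m <- mi - outer(t$colmean, t$colmean) / t$overall
      } else {
        m <- mi - (outer(t$colmean, rep(1, p)) +
                     outer(rep(1, p), t$colmean) - t$overall)
      }
      diag(m) <- 0
    }
  } else if (method == "OMES") {
    m <- matrix(0, p, p)
    for (i in seq_len(p - 1L))
      for (j in (i + 1L):p)
        m[i, j] <- m[j, i] <- .omes_codes(codes[, i], codes[, j], warn_few = FALSE)
  } else { # McBASC
    n <- nrow(codes)
    if (n < 3L) {
      warn("fewer than 3 rows; McBASC set to 0")
      m <- matrix(0, p, p)
    } else {
      rp <- .row_pairs(n)
      V <- vapply(seq_len(p),
                  function(c) .mcbasc_simvec(codes[, c], rp$k, rp$l, similarity),
                  numeric(length(rp$k)))
      m <- suppressWarnings(cor(V, use = "pairwise.complete.obs"))
      m[!is.finite(m)] <- 0
    }
  }
  diag(m) <- 0
  sp <- filtered$tm_column_map$seqpos
  dimnames(m) <- list(sp, sp)
  m
}

coev_pair <- function(filtered, i, j, method, ...) {
  ci <- tm_col_of(filtered, i); cj <- tm_col_of(filtered, j)
  if (is.na(ci) || is.na(cj)) abort("i and j must be TM sequence positions")
  full_coev_matrix(filtered, method, ...)[ci, cj]
}

#' Mutual information between two TM alignment columns
#'
#' Empirical mutual information `sum p(a,b) ln[p(a,b)/(p(a)p(b))]` over rows
#' that carry a standard residue at both positions. Natural logarithms.
#'
#' @param filtered A `tm_filtered_alignment`.
#' @param i,j Sequence positions (must lie in TM helices).
#' @return Non-negative score (0 with a warning when < 2 ungapped rows).
#' @export
mutual_information <- function(filtered, i, j) {
  ci <- tm_col_of(filtered, i); cj <- tm_col_of(filtered, j)
  if (is.na(ci) || is.na(cj)) abort("i and j must be TM sequence positions")
  codes <- codes_matrix(filtered)
  .mi_codes(codes[, ci], codes[, cj])
}

#' Phylogeny-corrected mutual information (MIp)
#'
#' Dunn et al.'s average-product correction: `MIp(i,j) = MI(i,j) -
#' MI(i,.) MI(j,.) / <MI>`, where `MI(i,.)` is the mean MI of column i
#' against all other TM columns and `<MI>` the overall off-diagonal mean.
#' `MIp` is 0 when `<MI>` is 0.
#'
#' @inheritParams mutual_information
#' @export
mip <- function(filtered, i, j) coev_pair(filtered, i, j, "MIp")

#' Background-corrected mutual information (MIc)
#'
#' A column-background correction of MI in the spirit of the average-product
#' correction. The default form is additive,
#' `MI(i,j) - (MI(i,.) + MI(j,.) - <MI>)`; the multiplicative (APC) form is
#' available via `correction = "apc"`.
#'
#' @inheritParams mutual_information
#' @param correction `"additive"` (default) or `"apc"`.
#' @export
mic <- function(filtered, i, j, correction = c("additive", "apc")) {
  coev_pair(filtered, i, j, "MIc", mic_correction = match.arg(correction))
}

#' Observed-minus-expected-squared (OMES) covariation score
#'
#' Over the `N` pairwise-ungapped rows, `sum_{a,b} (N_obs(a,b) -
#' N_ex(a,b))^2 / N` with `N_ex(a,b) = N(a) N(b) / N`.
#'
#' @inheritParams mutual_information
#' @export
omes <- function(filtered, i, j) {
  ci <- tm_col_of(filtered, i); cj <- tm_col_of(filtered, j)
  if (is.na(ci) || is.na(cj)) abort("i and j must be TM sequence positions")
  codes <- codes_matrix(filtered)
  .omes_codes(codes[, ci], codes[, cj])
}

#' McBASC substitution-correlation score
#'
#' For every unordered pair of rows the substitution-matrix similarity of
#' their residues is taken in column i and in column j; McBASC is the
#' Pearson correlation of the two similarity vectors (McLachlan matrix by
#' default). Row pairs with a gap at either column are skipped; zero
#' variance in either vector gives 0.
#'
#' @inheritParams mutual_information
#' @param similarity 20x20 residue similarity matrix in canonical order.
#' @export
mcbasc <- function(filtered, i, j, similarity = MCLACHLAN) {
  ci <- tm_col_of(filtered, i); cj <- tm_col_of(filtered, j)
  if (is.na(ci) || is.na(cj)) abort("i and j must be TM sequence positions")
  codes <- codes_matrix(filtered)
  n <- nrow(codes)
  if (n < 3L) { warn("fewer than 3 rows; McBASC set to 0"); return(0) }
  rp <- .row_pairs(n)
  si <- .mcbasc_simvec(codes[, ci], rp$k, rp$l, similarity)
  sj <- .mcbasc_simvec(codes[, cj], rp$k, rp$l, similarity)
  v <- !is.na(si) & !is.na(sj)
  if (sum(v) < 2L) return(0)
  r <- suppressWarnings(cor(si[v], sj[v]))
  if (!is.finite(r)) 0 else r
}

#' Standardized coevolution matrices for one chain
#'
#' Computes the configured correlated-mutation scores for every pair of TM
#' positions (including same-helix pairs, which feed the windowed encoding
#' but are never prediction candidates) and min-max standardizes each
#' method's scores across all scored pairs of the chain. The default method
#' set is MIc, OMES and McBASC; MI and MIp are available but not part of
#' the default feature set.
#'
#' @param filtered A `tm_filtered_alignment`.
#' @param methods Character vector of methods among
#'   `"MI","MIp","MIc","OMES","McBASC"`.
#' @param mic_correction Background correction for MIc.
#' @param similarity Similarity matrix for McBASC.
#' @return Named list of `tm_coevolution` objects, each with `method`,
#'   `raw` and `standardized` symmetric matrices (dimnames = sequence
#'   positions).
#' @export
coevolution_matrices <- function(filtered,
                                 methods = c("MIc", "OMES", "McBASC"),
                                 mic_correction = "additive",
                                 similarity = MCLACHLAN) {
  out <- lapply(methods, function(mth) {
    raw <- full_coev_matrix(filtered, mth, mic_correction = mic_correction,
                            similarity = similarity)
    ut <- upper.tri(raw)
    std <- raw
    std[ut] <- standardize_minmax(raw[ut])
    std[lower.tri(std)] <- t(std)[lower.tri(std)]
    diag(std) <- 0
    structure(list(method = mth, raw = raw, standardized = std),
              class = "tm_coevolution")
  })
  setNames(out, methods)
}

#' @export
print.tm_coevolution <- function(x, ...) {
  cat(sprintf("<tm_coevolution> %s over %d TM positions\n",
              x$method, ncol(x$raw)))
  invisible(x)
}

#' Export coevolution matrices as a long tibble
#'
#' @param matrices A list returned by [coevolution_matrices()].
#' @return Tibble with columns `i`, `j` (sequence positions, `i < j`),
#'   `method`, `raw`, `standardized`.
#' @export
coevolution_tbl <- function(matrices) {
  dplyr::bind_rows(lapply(matrices, function(m) {
    sp <- as.integer(rownames(m$raw))
    ut <- which(upper.tri(m$raw), arr.ind = TRUE)
    tibble(i = sp[ut[, 1]], j = sp[ut[, 2]], method = m$method,
           raw = m$raw[ut], standardized = m$standardized[ut])
  }))
}
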