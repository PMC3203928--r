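## Correlation-based feature selection (CFS): symmetric-uncertainty feature
## correlations over MDL-discretized features, subset merit, best-first
## search, and the 10-balanced-subset union protocol.

## Shannon entropy (log2) of a discrete vector
.H <- function(x) {
  p <- tabulate(match(x, unique(x)))
  p <- p / length(x)
  -sum(p * log2(p))
}

.H_joint <- function(x, y) .H(paste(x, y, sep = "\r"))

#' Symmetric uncertainty between two discrete features
#'
#' `U(X, Y) = 2 [H(X) + H(Y) - H(X, Y)] / [H(X) + H(Y)]`, a normalized
#' mutual information in `[0, 1]`. Inputs are treated as categorical;
#' continuous features should be discretized first (see
#' [discretize_mdl()]). When both entropies are zero the score is 0.
#'
#' @param x,y Vectors of equal length (>= 2), treated as categorical.
#' @return Value in `[0, 1]`; 1 for identical non-constant features.
#' @export
symmetric_uncertainty <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  hx <- .H(x); hy <- .H(y)
  if (hx + hy == 0) return(0)
  u <- 2 * (hx + hy - .H_joint(x, y)) / (hx + hy)
  min(max(u, 0), 1)
}

#' Supervised MDL discretization of a continuous feature
#'
#' Recursive binary splitting on class-information gain with the minimum
#' description length stopping criterion (Fayyad & Irani): a cut is accepted
#' when its gain exceeds `(log2(n-1) + log2(3^k - 2) - k H(S) + k1 H(S1) +
#' k2 H(S2)) / n`, with `k` the number of classes present. Features for
#' which no cut is accepted collapse to a single bin (and thus carry zero
#' symmetric uncertainty with the class).
#'
#' @param x Numeric feature.
#' @param y Class vector (same length).
#' @return Integer bin codes (1-based), with attribute `cuts`.
#' @export
discretize_mdl <- function(x, y) {
  stopifnot(length(x) == length(y))
  ord <- order(x)
  xs <- x[ord]; ys <- as.character(y[ord])
  cuts <- .mdl_cuts(xs, ys)
  bins <- findInterval(x, cuts) + 1L
  attr(bins, "cuts") <- cuts
  bins
}

.mdl_cuts <- function(xs, ys) {
  n <- length(xs)
  if (n < 2L) return(numeric(0))
  cls <- unique(ys)
  k <- length(cls)
  if (k < 2L || xs[1] == xs[n]) return(numeric(0))
  ## cumulative class counts let every candidate cut be scored at once
  ind <- matrix(0L, n, k)
  ind[cbind(seq_len(n), match(ys, cls))] <- 1L
  cum <- apply(ind, 2, cumsum)
  tot <- cum[n, ]
  cand <- which(diff(xs) > 0)  # midpoints between adjacent distinct values
  if (length(cand) == 0L) return(numeric(0))
  entvec <- function(cnt) {
    ntot <- rowSums(cnt)
    p <- cnt / ntot
    -rowSums(ifelse(p > 0, p * log2(p), 0))
  }
  cl <- cum[cand, , drop = FALSE]
  cr <- matrix(tot, length(cand), k, byrow = TRUE) - cl
  nl <- rowSums(cl); nr <- rowSums(cr)
  el <- entvec(cl); er <- entvec(cr)
  we <- (nl / n) * el + (nr / n) * er
  b <- which.min(we)
  es <- entvec(matrix(tot, 1))
  gain <- es - we[b]
  k1 <- sum(cl[b, ] > 0); k2 <- sum(cr[b, ] > 0)
  delta <- log2(3^k - 2) - (k * es - k1 * el[b] - k2 * er[b])
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  d <- cand[b]
  cut <- (xs[d] + xs[d + 1]) / 2
  sort(c(.mdl_cuts(xs[1:d], ys[1:d]),
         cut,
         .mdl_cuts(xs[(d + 1):n], ys[(d + 1):n])))
}

#' CFS merit of a feature subset
#'
#' `Merit = k r_cf / sqrt(k + k (k - 1) r_ff)` where `r_cf` is the mean
#' symmetric uncertainty between subset features and the class and `r_ff`
#' the mean pairwise symmetric uncertainty within the subset. Rewards
#' class-predictive features, penalizes redundancy; the merit of a single
#' feature equals its `U(f, C)`.
#'
#' @param features Matrix or data frame of (discretized) feature columns.
#' @param class_col Class vector.
#' @param subset Column indices of the evaluated subset (default: all).
#' @return The merit (0 for an empty subset).
#' @export
cfs_merit <- function(features, class_col, subset = seq_len(ncol(features))) {
  features <- as.matrix(features)
  k <- length(subset)
  if (k == 0L) return(0)
  rcf <- mean(vapply(subset, function(f)
    symmetric_uncertainty(features[, f], class_col), numeric(1)))
  if (k == 1L) return(rcf)
  pairs <- utils::combn(subset, 2)
  rff <- mean(vapply(seq_len(ncol(pairs)), function(p)
    symmetric_uncertainty(features[, pairs[1, p]], features[, pairs[2, p]]),
    numeric(1)))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

## merit with cached U values (used by the search)
.merit_cached <- function(subset, su_class, su_pair) {
  k <- length(subset)
  if (k == 0L) return(0)
  rcf <- mean(su_class[subset])
  if (k == 1L) return(rcf)
  s <- 0
  for (a in 1:(k - 1)) for (b in (a + 1):k)
    s <- s + su_pair(subset[a], subset[b])
  k * rcf / sqrt(k + k * (k - 1) * (s / (k * (k - 1) / 2)))
}

#' Best-first forward search for a high-merit feature subset
#'
#' Greedy best-first search over feature subsets: an open list ordered by
#' merit, expansion by single-feature additions, stopping after
#' `stall_limit` consecutive expansions that fail to improve the best merit
#' seen. Deterministic: ties are broken by lowest feature index.
#'
#' @param features Matrix of feature columns.
#' @param class_col Class vector.
#' @param stall_limit Consecutive non-improving expansions allowed
#'   (default 5).
#' @param discretize Discretize continuous columns with [discretize_mdl()]
#'   first (default TRUE).
#' @return Integer vector of selected feature indices (with attribute
#'   `merit`).
#' @export
best_first_search <- function(features, class_col, stall_limit = 5,
                              discretize = TRUE) {
  features <- as.matrix(features)
  M <- ncol(features)
  disc <- if (discretize)
    vapply(seq_len(M), function(f) as.integer(discretize_mdl(features[, f], class_col)),
           integer(nrow(features)))
  else features
  su_class <- vapply(seq_len(M), function(f)
    symmetric_uncertainty(disc[, f], class_col), numeric(1))
  cache <- new.env(parent = emptyenv())
  su_pair <- function(a, b) {
    key <- paste0(min(a, b), ".", max(a, b))
    v <- cache[[key]]
    if (is.null(v)) {
      v <- symmetric_uncertainty(disc[, a], disc[, b])
      cache[[key]] <- v
    }
    v
  }

  seen <- new.env(parent = emptyenv())
  set_key <- function(s) paste0("s", paste(sort(s), collapse = ","))
  open_sets <- list(integer(0))
  open_merit <- 0
  seen[[set_key(integer(0))]] <- TRUE
  best_set <- integer(0); best_merit <- 0
  stall <- 0L

  while (length(open_sets) > 0L && stall < stall_limit) {
    pick <- which.max(open_merit)  # first max = earliest inserted, lowest index
    cur <- open_sets[[pick]]; cur_merit <- open_merit[pick]
    open_sets <- open_sets[-pick]; open_merit <- open_merit[-pick]
    if (cur_merit > best_merit + 1e-10) {
      best_merit <- cur_merit; best_set <- cur; stall <- 0L
    } else if (length(cur) > 0L) {
      stall <- stall + 1L
    }
    for (f in setdiff(seq_len(M), cur)) {
      child <- sort(c(cur, f))
      key <- set_key(child)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      m <- .merit_cached(child, su_class, su_pair)
      open_sets[[length(open_sets) + 1L]] <- child
      open_merit <- c(open_merit, m)
    }
  }
  structure(sort(best_set), merit = best_merit)
}

#' CFS over balanced subsamples with union of the selected subsets
#'
#' Draws `n_subsets` balanced subsamples -- all contact pairs plus an equal
#' number of randomly chosen non-contact pairs (positives are downsampled
#' instead when negatives are scarce) -- runs [best_first_search()] on each,
#' and unions the selected subsets into the final feature set.
#'
#' @param pairs A labeled `tm_pairs` dataset (or a row-bound collection).
#' @param label Which label column to use: `"DEF1"` or `"DEF2"`.
#' @param n_subsets Number of balanced subsamples (default 10).
#' @param seed Integer seed; recorded in the result.
#' @param stall_limit Passed to [best_first_search()].
#' @return A `tm_cfs` object: `subsets` (list of per-subsample index sets),
#'   `union` (sorted indices), `scores` tibble (`feature`, `mean_score`,
#'   `n_subsets_selected`), `seed`.
#' @export
select_features <- function(pairs, label = "DEF1", n_subsets = 10, seed = 1,
                            stall_limit = 5) {
  lab_col <- paste0("label_", label)
  if (!lab_col %in% names(pairs)) abort(sprintf("no %s column", lab_col))
  y <- pairs[[lab_col]]
  X <- pairs$features
  pos <- which(y); neg <- which(!y)
  if (length(pos) == 0L) abort("no positive (contact) pairs")
  M <- ncol(X)
  subsets <- vector("list", n_subsets)
  score_sum <- numeric(M); sel_count <- integer(M)
  for (s in seq_len(n_subsets)) {
    set.seed(seed + s)
    if (length(neg) >= length(pos)) {
      idx <- c(pos, sample(neg, length(pos)))
    } else {
      idx <- c(sample(pos, length(neg)), neg)
    }
    Xs <- X[idx, , drop = FALSE]; ys <- y[idx]
    disc <- vapply(seq_len(M), function(f)
      as.integer(discretize_mdl(Xs[, f], ys)), integer(length(idx)))
    score_sum <- score_sum + vapply(seq_len(M), function(f)
      symmetric_uncertainty(disc[, f], ys), numeric(1))
    sel <- best_first_search(disc, ys, stall_limit = stall_limit,
                             discretize = FALSE)
    subsets[[s]] <- as.integer(sel)
    sel_count[sel] <- sel_count[sel] + 1L
  }
  union_set <- sort(unique(unlist(subsets)))
  structure(list(
    subsets = subsets,
    union = union_set,
    scores = tibble(feature = colnames(X) %||% as.character(seq_len(M)),
                    mean_score = score_sum / n_subsets,
                    n_subsets_selected = sel_count),
    label = label, seed = seed),
    class = "tm_cfs")
}

#' @export
print.tm_cfs <- function(x, ...) {
  cat(sprintf("<tm_cfs> %d subsets, union of %d features (label %s)\n",
              length(x$subsets), length(x$union), x$label))
  invisible(x)
}

#' @rdname select_features
#' @param x A `tm_cfs` object.
#' @param ... Unused.
#' @export
tidy.tm_cfs <- function(x, ...) {
  dplyr::arrange(
    dplyr::mutate(x$scores, selected = x$scores$n_subsets_selected > 0),
    dplyr::desc(.data$mean_score))
}
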