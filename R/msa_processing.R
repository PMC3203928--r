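#' Min-max standardization to the unit interval
#'
#' Maps `x` to `(x - min)/(max - min)`. Used to put correlated-mutation and
#' conservation scores of one chain on a common `[0, 1]` scale before
#' encoding. When all values are equal the scores carry no signal and every
#' value maps to 0.
#'
#' @param x Numeric vector (non-empty; NAs ignored for the range).
#' @return Numeric vector in `[0, 1]`.
#' @export
standardize_minmax <- function(x) {
  if (length(x) == 0L) abort("cannot standardize an empty vector")
  lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
  if (!is.finite(lo) || !is.finite(hi) || hi == lo) return(rep(0, length(x)))
  (x - lo) / (hi - lo)
}

#' Filter an alignment down to reliable transmembrane columns and rows
#'
#' Applies, in order, the three filtering rules used before scoring
#' coevolution:
#' \enumerate{
#'   \item drop alignment columns that do not map to a TM-helix (`H`)
#'     position of the query;
#'   \item drop any row with >= `max_gap_frac` gap characters within any
#'     single TM segment;
#'   \item enforce pairwise sequence identity <= `max_identity`, computed
#'     over TM columns only, by greedy top-down retention (the query row is
#'     always kept; a row is dropped when it exceeds the identity bound
#'     against any already-kept row).
#' }
#'
#' @param aln A `tm_alignment` whose query row matches `protein$sequence`.
#' @param protein The `tm_protein` providing topology.
#' @param max_identity Pairwise identity bound over TM columns (default 0.90).
#' @param max_gap_frac Per-segment gap fraction threshold (default 0.25,
#'   applied as `>=`).
#' @return A `tm_filtered_alignment`: `mat` (kept rows x TM columns),
#'   `kept_rows` (indices into the original alignment), and `tm_column_map`
#'   (tibble: `col`, `seqpos`, `helix_index`, `pos_in_helix`).
#' @export
filter_msa <- function(aln, protein, max_identity = 0.90, max_gap_frac = 0.25) {
  query <- gsub("-", "", paste0(aln$mat[1, ], collapse = ""))
  if (toupper(query) != protein$sequence)
    abort("query row of the alignment does not reconstruct the protein sequence")

  topo <- strsplit(protein$topology, "")[[1]]
  ## rule 1: TM columns only
  keep_cols <- which(!is.na(aln$column_map) & topo[aln$column_map] == "H")
  if (length(keep_cols) == 0L) abort("no TM columns in alignment")
  seqpos <- aln$column_map[keep_cols]
  hx <- protein$helices
  helix_of <- rep(NA_integer_, nchar(protein$sequence))
  for (h in seq_len(nrow(hx)))
    helix_of[hx$start[h]:hx$end[h]] <- hx$helix_index[h]
  tm_column_map <- tibble(
    col = seq_along(keep_cols),
    seqpos = seqpos,
    helix_index = helix_of[seqpos],
    pos_in_helix = seqpos - hx$start[helix_of[seqpos]] + 1L)

  mat <- aln$mat[, keep_cols, drop = FALSE]
  mat[matrix(is_gaplike(mat), nrow = nrow(mat))] <- "-"

  ## rule 2: rows with >= 25% gaps in any single TM segment
  gap <- mat == "-"
  seg_bad <- rep(FALSE, nrow(mat))
  for (h in unique(tm_column_map$helix_index)) {
    cols <- tm_column_map$col[tm_column_map$helix_index == h]
    frac <- rowMeans(gap[, cols, drop = FALSE])
    seg_bad <- seg_bad | frac >= max_gap_frac
  }
  seg_bad[1] <- FALSE  # query always retained
  rows2 <- which(!seg_bad)

  ## rule 3: greedy top-down identity pruning over TM columns
  m2 <- mat[rows2, , drop = FALSE]
  kept <- 1L
  for (r in seq_len(nrow(m2))[-1]) {
    ident <- vapply(kept, function(k) mean(m2[k, ] == m2[r, ]), numeric(1))
    if (all(ident <= max_identity)) kept <- c(kept, r)
  }
  kept_rows <- rows2[kept]

  out <- structure(
    list(mat = mat[kept_rows, , drop = FALSE],
         kept_rows = kept_rows,
         tm_column_map = tm_column_map,
         n_rows = length(kept_rows)),
    class = "tm_filtered_alignment")
  if (length(kept_rows) < 2L)
    warn("fewer than 2 rows survive filtering; coevolution scores are undefined")
  out
}

#' @export
print.tm_filtered_alignment <- function(x, ...) {
  cat(sprintf("<tm_filtered_alignment> %d rows x %d TM columns (%d helices)\n",
              nrow(x$mat), ncol(x$mat), length(unique(x$tm_column_map$helix_index))))
  invisible(x)
}

## column index in the filtered matrix for a sequence position (NA if not TM)
tm_col_of <- function(filtered, seqpos) {
  filtered$tm_column_map$col[match(seqpos, filtered$tm_column_map$seqpos)]
}

#' Positional conservation from Shannon entropy
#'
#' For every TM column of a filtered alignment, the Shannon entropy
#' `H = -sum f_a ln f_a` of its residue frequencies (gaps excluded from the
#' denominator; an all-gap column has `H = 0`), followed by min-max
#' standardization across all TM positions of the chain. Natural logarithms
#' are used; the standardization makes the score invariant to the log base.
#'
#' @param filtered A `tm_filtered_alignment`.
#' @return A `tm_conservation` tibble: `seqpos`, `helix_index`,
#'   `pos_in_helix`, `entropy`, `standardized`.
#' @export
conservation <- function(filtered) {
  if (nrow(filtered$mat) < 1L) abort("conservation needs at least one row")
  ent <- apply(filtered$mat, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return(0)
    f <- tabulate(aa_code(col), nbins = 20)
    f <- f[f > 0] / sum(f)
    -sum(f * log(f))
  })
  out <- filtered$tm_column_map
  out$entropy <- as.numeric(ent)
  out$standardized <- standardize_minmax(out$entropy)
  class(out) <- c("tm_conservation", class(tibble()))
  out
}
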