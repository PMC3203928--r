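## Canonical amino-acid order used for every 20-component profile row and
## for frequency counting. Fixed throughout the package.
AA_ORDER <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Residue codes treated as gaps when counting frequencies: alignment gap
## characters plus ambiguous / non-standard one-letter codes.
GAPLIKE <- c("-", ".", "B", "Z", "X", "U", "O", "J", "*")

## McLachlan (1972) amino-acid similarity matrix, row/column order AA_ORDER.
## Historical choice of the McBASC correlated-mutation score.
MCLACHLAN <- matrix(c(
  8, 1, 3, 4, 1, 3, 3, 2, 3, 2, 3, 3, 4, 3, 2, 4, 3, 3, 1, 1,
  1, 9, 1, 0, 0, 1, 3, 1, 0, 0, 3, 1, 0, 0, 1, 2, 2, 1, 2, 1,
  3, 1, 8, 5, 1, 3, 4, 1, 3, 1, 2, 5, 3, 4, 1, 3, 3, 1, 0, 1,
  4, 0, 5, 8, 0, 3, 2, 1, 4, 1, 1, 4, 4, 5, 3, 4, 4, 2, 1, 2,
  1, 0, 1, 0, 9, 0, 4, 3, 0, 5, 5, 0, 1, 0, 1, 2, 1, 3, 6, 6,
  3, 1, 3, 3, 0, 8, 2, 1, 3, 1, 1, 3, 3, 2, 3, 3, 2, 2, 1, 0,
  3, 3, 4, 2, 4, 2, 8, 2, 4, 2, 3, 4, 3, 4, 5, 3, 4, 2, 3, 4,
  2, 1, 1, 1, 3, 1, 2, 8, 1, 5, 5, 1, 1, 0, 1, 2, 3, 5, 3, 3,
  3, 0, 3, 4, 0, 3, 4, 1, 8, 2, 1, 4, 3, 4, 5, 3, 3, 2, 1, 1,
  2, 0, 1, 1, 5, 1, 2, 5, 2, 8, 6, 1, 1, 3, 2, 2, 3, 5, 3, 3,
  3, 3, 2, 1, 5, 1, 3, 5, 1, 6, 8, 2, 1, 3, 1, 2, 3, 4, 1, 2,
  3, 1, 5, 4, 0, 3, 4, 1, 4, 1, 2, 8, 1, 4, 3, 5, 3, 1, 0, 2,
  4, 0, 3, 4, 1, 3, 3, 1, 3, 1, 1, 1, 8, 3, 3, 3, 3, 2, 0, 0,
  3, 0, 4, 5, 0, 2, 4, 0, 4, 3, 3, 4, 3, 8, 5, 4, 3, 2, 2, 1,
  2, 1, 1, 3, 1, 3, 5, 1, 5, 2, 1, 3, 3, 5, 8, 4, 3, 2, 3, 2,
  4, 2, 3, 4, 2, 3, 3, 2, 3, 2, 2, 5, 3, 4, 4, 8, 5, 2, 3, 3,
  3, 2, 3, 4, 1, 2, 4, 3, 3, 3, 3, 3, 3, 3, 3, 5, 8, 3, 2, 1,
  3, 1, 1, 2, 3, 2, 2, 5, 2, 5, 4, 1, 2, 2, 2, 2, 3, 8, 2, 3,
  1, 2, 0, 1, 6, 1, 3, 3, 1, 3, 1, 0, 0, 2, 3, 3, 2, 2, 9, 6,
  1, 1, 1, 2, 6, 0, 4, 3, 1, 3, 2, 2, 0, 1, 2, 3, 1, 3, 6, 9),
  nrow = 20, byrow = TRUE, dimnames = list(AA_ORDER, AA_ORDER))

## encode residue characters as integers 1..20 (0 = gap-like / unknown)
aa_code <- function(x) {
  idx <- match(x, AA_ORDER)
  idx[is.na(idx)] <- 0L
  idx
}

is_gaplike <- function(x) x %in% GAPLIKE | !(x %in% AA_ORDER)
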