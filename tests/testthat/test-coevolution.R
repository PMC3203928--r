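test_that("mutual information matches closed forms", {
  ## two constant columns
  fa <- filtered_from_rows(c("AL", "AL", "AL", "AL"))
  expect_equal(mutual_information(fa, 1, 2), 0)
  ## perfectly covarying 2-state columns, 50/50 split
  fa2 <- filtered_from_rows(c("AL", "AL", "RW", "RW"))
  expect_equal(mutual_information(fa2, 1, 2), log(2), tolerance = 1e-12)
})

test_that("each score equals its brute-force oracle on toy alignments", {
  fa <- filtered_from_rows(c("ALWRD", "ALWAD", "RWWRC", "RLARC", "AWLRD",
                             "RLWAC"))
  cols <- aln_cols(fa)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(mutual_information(fa, i, j), oracle_mi(cols[[i]], cols[[j]]),
                 tolerance = 1e-12)
    expect_equal(omes(fa, i, j), oracle_omes(cols[[i]], cols[[j]]),
                 tolerance = 1e-12)
    expect_equal(mcbasc(fa, i, j), oracle_mcbasc(cols[[i]], cols[[j]]),
                 tolerance = 1e-12)
  }
  mip_o <- oracle_mip_matrix(cols)
  mic_o <- oracle_mic_matrix(cols)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(mip(fa, i, j), mip_o[i, j], tolerance = 1e-12)
    expect_equal(mic(fa, i, j), mic_o[i, j], tolerance = 1e-12)
  }
})

test_that("OMES on the 2x2 balanced covarying table is exact", {
  fa <- filtered_from_rows(c("AA", "AA", "RR", "RR"))
  ## all four occupied/expected cells deviate by 1: 4 * 1 / 4 = 1
  expect_equal(omes(fa, 1, 2), 1)
  expect_equal(omes(fa, 1, 2), oracle_omes(fa$mat[, 1], fa$mat[, 2]))
})

test_that("a uniform MI field collapses MIp and MIc to zero", {
  ## three identical (perfectly coupled) columns: all off-diagonal MI equal
  fa <- filtered_from_rows(c("AAA", "AAA", "RRR", "RRR", "WWW", "WWW"))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(mip(fa, i, j), 0, tolerance = 1e-12)
    expect_equal(mic(fa, i, j), 0, tolerance = 1e-12)
  }
})

test_that("McBASC closed forms: self-correlation 1, constant column 0", {
  fa <- filtered_from_rows(c("ALA", "ALA", "RWA", "WRA", "LAA"))
  expect_equal(mcbasc(fa, 1, 1), 1.0)  # same column correlates perfectly
  expect_equal(mcbasc(fa, 1, 3), 0)    # constant column: zero variance
})

test_that("all scores are symmetric and row-permutation invariant", {
  set.seed(11)
  rows <- random_alignment_rows(7, 5, gap_prob = 0.15)
  fa <- filtered_from_rows(rows)
  fa_perm <- filtered_from_rows(rows[c(1, 5, 3, 7, 2, 6, 4)])
  for (f in list(mutual_information, mip, mic, omes, mcbasc)) {
    expect_equal(suppressWarnings(f(fa, 2, 4)),
                 suppressWarnings(f(fa, 4, 2)), tolerance = 1e-12)
    expect_equal(suppressWarnings(f(fa, 2, 4)),
                 suppressWarnings(f(fa_perm, 2, 4)), tolerance = 1e-12)
  }
})

test_that("the default matrix set is MIc/OMES/McBASC, standardized", {
  fa <- filtered_from_rows(c("ALWRD", "ALWAD", "RWWRC", "RLARC", "AWLRD"))
  mats <- coevolution_matrices(fa)
  expect_named(mats, c("MIc", "OMES", "McBASC"))
  for (m in mats) {
    expect_equal(m$raw, t(m$raw))
    ut <- m$standardized[upper.tri(m$standardized)]
    expect_true(all(ut >= 0 & ut <= 1))
    if (length(unique(round(m$raw[upper.tri(m$raw)], 12))) >= 2) {
      expect_equal(min(ut), 0)
      expect_equal(max(ut), 1)
    }
  }
})

test_that("MI is non-negative; corrected scores may go negative", {
  set.seed(23)
  for (rep in 1:10) {
    fa <- suppressWarnings(
      filtered_from_rows(random_alignment_rows(6, 4, gap_prob = 0.2)))
    for (i in 1:3) for (j in (i + 1):4)
      expect_gte(suppressWarnings(mutual_information(fa, i, j)), 0)
  }
})

test_that("a planted covarying pair ranks in the top 1% for every method", {
  spec <- planted_msa_spec(n_cols = 25, n_rows = 200,
                           planted_pairs = data.frame(col_i = 5, col_j = 17,
                                                      coupling = 1),
                           seed = 31)
  msa <- make_msa(spec)
  prot <- parse_topology(paste0(msa$mat[1, ], collapse = ""), strrep("H", 25))
  fa <- filter_msa(msa, prot)
  mats <- coevolution_matrices(fa, methods = c("MIp", "MIc", "OMES", "McBASC"))
  sp <- as.integer(rownames(mats[[1]]$raw))
  i5 <- match(5, sp); i17 <- match(17, sp)
  for (m in mats) {
    vals <- m$raw[upper.tri(m$raw)]
    planted_val <- m$raw[i5, i17]
    rank_frac <- mean(vals >= planted_val)
    expect_lte(rank_frac, 0.01)
  }
})
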