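test_that("profile windows zero-fill beyond the termini", {
  prof <- matrix(runif(200), 10, 20, dimnames = list(NULL, NULL))
  w1 <- encode_profile_window(prof, 1)
  expect_length(w1, 180)
  expect_equal(unname(w1[1:80]), rep(0, 80))       # offsets -4..-1 absent
  expect_equal(unname(w1[81:100]), prof[1, ])      # centre row verbatim
  w5 <- encode_profile_window(prof, 5)
  expect_equal(unname(w5), as.numeric(t(prof[1:9, ])))
  expect_error(encode_profile_window(prof, 11), "outside")
  ## nonzero 20-blocks equal the residues available in range
  for (sp in 1:10) {
    w <- encode_profile_window(prof, sp)
    blocks <- matrix(w, nrow = 20)
    expect_equal(sum(colSums(abs(blocks)) > 0),
                 length(max(1, sp - 4):min(10, sp + 4)))
  }
})

test_that("coevolution windows follow membrane orientation and zero-fill", {
  ch <- prepared_chain(seed = 6)
  prot <- ch$protein
  hx <- prot$helices
  i <- hx$start[1] + 5; j <- hx$start[2] + 5
  w <- encode_coevolution_window(ch$matrices, prot, i, j)
  expect_length(w, 27)
  sp <- as.integer(rownames(ch$matrices$MIc$standardized))
  expect_equal(unname(w[5]),
               ch$matrices$MIc$standardized[match(i, sp), match(j, sp)])
  ## a pair at a helix end has truncated offsets
  w_end <- encode_coevolution_window(ch$matrices, prot, hx$start[1], j)
  expect_true(any(w_end[1:4] == 0))
  expect_error(encode_coevolution_window(ch$matrices, prot, i, i + 1),
               "different TM helices")
})

test_that("orientation flips the window direction for 'outside' helices", {
  ch <- prepared_chain(seed = 6)
  prot <- ch$protein
  hx <- prot$helices
  expect_equal(hx$n_term_side[1:2], c("inside", "outside"))
  i <- hx$start[1] + 5; j <- hx$start[2] + 5
  w <- encode_coevolution_window(ch$matrices, prot, i, j)
  sp <- as.integer(rownames(ch$matrices$MIc$standardized))
  ## offset +1: helix 1 advances N->C, helix 2 (outside) advances C->N
  expect_equal(unname(w[6]),
               ch$matrices$MIc$standardized[match(i + 1, sp), match(j - 1, sp)])
})

test_that("conservation windows cover nine positions, zero outside TM", {
  ch <- prepared_chain(seed = 6)
  hx <- ch$protein$helices
  w <- encode_conservation_window(ch$cons, hx$start[1])
  expect_length(w, 9)
  expect_equal(unname(w[1:4]), rep(0, 4))   # loop positions before the helix
  i <- hx$start[1] + 5
  w2 <- encode_conservation_window(ch$cons, i)
  expect_equal(unname(w2[5]),
               ch$cons$standardized[match(i, ch$cons$seqpos)])
})

test_that("relative distance follows |p1/l1 - p2/l2|", {
  expect_equal(relative_distance(1, 10, 1, 10), 0)
  expect_equal(relative_distance(10, 10, 1, 10), 0.9)
  expect_equal(relative_distance(3, 6, 1, 2), 0)
  expect_error(relative_distance(0, 10, 1, 10), "1 <= p <= l")
  expect_error(relative_distance(11, 10, 1, 10), "1 <= p <= l")
})

test_that("the candidate universe and 408-component vectors are correct", {
  ch <- prepared_chain(seed = 3, n_helices = 2, helix_length = 5,
                       axis_distance = 9)
  d <- ch$pairs
  expect_equal(nrow(d), 25L)                   # 5 x 5 inter-helix pairs
  expect_equal(ncol(d$features), 408L)
  expect_false(any(duplicated(paste(d$seqpos_i, d$seqpos_j))))
  expect_true(all(d$helix_a < d$helix_b))
  ## block sizes by name prefix
  cn <- colnames(d$features)
  expect_equal(sum(startsWith(cn, "prof_")), 360L)
  expect_equal(sum(startsWith(cn, "coev_")), 27L)
  expect_equal(sum(startsWith(cn, "cons_")), 18L)
  expect_true(all(c("rel_dist", "seq_sep", "n_helices") %in% cn))
  expect_true(all(d$features[, "rel_dist"] >= 0 & d$features[, "rel_dist"] < 1))
  expect_equal(unname(d$features[, "n_helices"]), rep(2, 25))
  expect_equal(unname(d$features[, "seq_sep"]),
               abs(d$seqpos_i - d$seqpos_j))
})

test_that("labels agree with the contact maps", {
  ch <- prepared_chain(seed = 8)
  d <- ch$pairs
  for (def in c("DEF1", "DEF2")) {
    cm <- ch$contact_maps[[def]]
    key <- paste(cm$contacts$seqpos_i, cm$contacts$seqpos_j)
    expect_equal(d[[paste0("label_", def)]],
                 paste(d$seqpos_i, d$seqpos_j) %in% key)
  }
})

test_that("encoding is deterministic", {
  ch1 <- prepared_chain(seed = 12)
  ch2 <- prepared_chain(seed = 12)
  expect_identical(ch1$pairs$features, ch2$pairs$features)
})

test_that("a single-helix chain yields an empty dataset with a warning", {
  b <- make_bundle(bundle_spec(n_helices = 2, helix_length = 6,
                               axis_distance = 9, seed = 2), "x")
  prot <- b$protein
  ## restrict to one helix by rewriting the topology
  topo <- strsplit(prot$topology, "")[[1]]
  h2 <- prot$helices$start[2]:prot$helices$end[2]
  topo[h2] <- "I"
  p1 <- parse_topology(prot$sequence, paste0(topo, collapse = ""))
  msa <- make_msa(planted_msa_spec(n_cols = nchar(p1$sequence), n_rows = 30,
                                   seed = 1))
  msa$mat[1, ] <- strsplit(p1$sequence, "")[[1]]
  fa <- filter_msa(msa, p1)
  mats <- coevolution_matrices(fa)
  cons <- conservation(fa)
  prof <- profile_from_msa(msa)
  expect_warning(d <- build_pair_dataset(p1, prof, mats, cons), "fewer than 2")
  expect_equal(nrow(d), 0L)
})
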