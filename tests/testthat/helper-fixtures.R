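## Shared fixture builders. Everything is generated in code at test time.

## A filtered alignment over an all-helix chain, with no rows or columns
## removed (identity/gap thresholds disabled), so coevolution scores can be
## checked against brute-force oracles on arbitrary alignments.
filtered_from_rows <- function(rows) {
  aln <- alignment_matrix(rows)
  q <- gsub("-", "", toupper(rows[1]))
  prot <- parse_topology(q, strrep("H", nchar(q)))
  suppressWarnings(filter_msa(aln, prot, max_identity = 1, max_gap_frac = 2))
}

## random alignment: gap-free query, optional gaps elsewhere
random_alignment_rows <- function(n_rows, n_cols, alphabet = c("A", "R", "L", "W"),
                                  gap_prob = 0.1) {
  q <- paste0(sample(alphabet, n_cols, replace = TRUE), collapse = "")
  others <- vapply(seq_len(n_rows - 1L), function(i) {
    ch <- sample(alphabet, n_cols, replace = TRUE)
    ch[runif(n_cols) < gap_prob] <- "-"
    paste0(ch, collapse = "")
  }, character(1))
  c(q, others)
}

## a protein with hand-placed atoms: `atoms` is a data.frame-like with
## seqpos, atom, x, y, z; resnames derived from the sequence
protein_with_atoms <- function(sequence, topology, atoms, chain_id = "toy") {
  p <- parse_topology(sequence, topology, chain_id)
  seq1 <- strsplit(p$sequence, "")[[1]]
  p$coords <- tibble::tibble(
    seqpos = as.integer(atoms$seqpos),
    resname = bio3d::aa123(seq1[atoms$seqpos]),
    atom = atoms$atom,
    element = substr(atoms$atom, 1, 1),
    x = atoms$x, y = atoms$y, z = atoms$z)
  p
}

## deterministic tiny two-helix chain with one atom per residue placed on
## two parallel lines `gap` apart (residue i of helix 1 faces residue i of
## helix 2)
two_line_protein <- function(len = 5, gap = 5.0) {
  seq <- strrep("L", 2 * len + 3)
  topo <- paste0("I", strrep("H", len), "O", strrep("H", len), "I")
  at <- rbind(
    data.frame(seqpos = 1 + seq_len(len), atom = "CA",
               x = 0, y = 0, z = 1.5 * seq_len(len)),
    data.frame(seqpos = len + 2 + seq_len(len), atom = "CA",
               x = gap, y = 0, z = 1.5 * seq_len(len)))
  protein_with_atoms(seq, topo, at)
}

## quick full-pipeline chain: bundle + planted MSA + derived features
prepared_chain <- function(seed = 3, n_helices = 3, helix_length = 12,
                           axis_distance = 9, n_rows = 60) {
  b <- make_bundle(bundle_spec(n_helices = n_helices,
                               helix_length = helix_length,
                               axis_distance = axis_distance, seed = seed),
                   chain_id = paste0("fix", seed))
  prot <- b$protein
  msa <- make_msa(planted_msa_spec(n_cols = nchar(prot$sequence),
                                   n_rows = n_rows, seed = seed + 1))
  prot$sequence <- paste0(msa$mat[1, ], collapse = "")
  prot$coords$resname <- bio3d::aa123(
    strsplit(prot$sequence, "")[[1]][prot$coords$seqpos])
  cms <- list(DEF1 = label_contacts(prot, "DEF1"),
              DEF2 = label_contacts(prot, "DEF2"))
  filtered <- filter_msa(msa, prot)
  mats <- coevolution_matrices(filtered)
  cons <- conservation(filtered)
  prof <- profile_from_msa(msa)
  pairs <- build_pair_dataset(prot, prof, mats, cons, cms)
  list(protein = prot, pairs = pairs, contact_maps = cms,
       filtered = filtered, matrices = mats, cons = cons, profile = prof)
}
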