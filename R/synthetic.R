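## Synthetic fixtures: ideal alpha-helix bundles with known geometry and
## multiple sequence alignments with planted covarying column pairs. Ground
## truth contacts are always recomputed from the generated coordinates by
## label_contacts(), keeping the generator and the labeler independent.

## hydrophobic-enriched residue frequencies typical of TM segments
## (no Gly/Pro inside the synthetic helices, so the fixtures exercise the
## plain C-beta rule; Gly-specific behavior is tested with hand-built
## coordinates)
TM_HELIX_FREQ <- local({
  f <- setNames(rep(0.5, 20), AA_ORDER)
  f[c("L", "I", "V", "F", "A", "M")] <- 4
  f[c("T", "S", "W", "Y", "C")] <- 1.5
  f[c("G", "P")] <- 0
  f / sum(f)
})

LOOP_FREQ <- local({
  f <- setNames(rep(1, 20), AA_ORDER)
  f[c("G", "S", "N", "D", "K", "R", "P", "E", "Q")] <- 3
  f / sum(f)
})

#' Specification of an ideal helix-bundle fixture
#'
#' Standard ideal alpha-helix geometry: 1.5 Angstrom rise and 100 degrees
#' twist per residue, C-alpha atoms at 2.3 Angstrom from the helix axis,
#' plus a pseudo C-beta placed 1.53 Angstrom beyond the C-alpha along the
#' outward normal (no full side chains). Helices alternate up/down through
#' the membrane and sit at the vertices of a regular polygon with the given
#' inter-axis spacing.
#'
#' @param n_helices Number of TM helices (>= 2).
#' @param helix_length Residues per helix.
#' @param axis_distance Distance between adjacent helix axes in Angstrom
#'   (>= 4; smaller would clash).
#' @param crossing_angle Tilt of alternate helices in degrees.
#' @param rise_per_residue,twist_per_residue,ca_radius Helix geometry.
#' @param loop_length Residues in each connecting loop (no coordinates).
#' @param seed Integer seed; regeneration is bit-identical.
#' @return A `tm_bundle_spec` list.
#' @export
bundle_spec <- function(n_helices = 3, helix_length = 16, axis_distance = 9,
                        crossing_angle = 0, rise_per_residue = 1.5,
                        twist_per_residue = 100, ca_radius = 2.3,
                        loop_length = 4, seed = 1) {
  stopifnot(n_helices >= 2, helix_length >= 1, rise_per_residue > 0,
            twist_per_residue > 0, ca_radius > 0, loop_length >= 0)
  if (axis_distance < 4)
    abort("axis_distance < 4 Angstrom: helices would overlap")
  structure(as.list(environment()), class = "tm_bundle_spec")
}

sample_aa <- function(n, freq) sample(AA_ORDER, n, replace = TRUE, prob = freq)

#' Generate an ideal helix bundle with coordinates and contact labels
#'
#' Builds a `tm_protein` with topology, sequence, C-alpha/pseudo-C-beta
#' coordinates for every helix residue (loop residues stay
#' coordinate-less), and computes the DEF1/DEF2 contact maps from the
#' coordinates via [label_contacts()].
#'
#' @param spec A [bundle_spec()].
#' @param chain_id Chain identifier.
#' @return A list: `protein` (with coordinates), `contact_maps`
#'   (`list(DEF1 = ..., DEF2 = ...)`), `spec`.
#' @export
make_bundle <- function(spec, chain_id = "bundle") {
  set.seed(spec$seed)
  n <- spec$n_helices
  len <- spec$helix_length
  ## axis centers: segment for 2 helices, regular polygon otherwise
  if (n == 2L) {
    centers <- rbind(c(0, 0), c(spec$axis_distance, 0))
  } else {
    R <- spec$axis_distance / (2 * sin(pi / n))
    ang <- 2 * pi * (seq_len(n) - 1) / n
    centers <- cbind(R * cos(ang), R * sin(ang))
  }
  up <- rep(c(TRUE, FALSE), length.out = n)

  ## sequence + topology
  seq_chars <- character(0); topo_chars <- character(0)
  helix_range <- matrix(0L, n, 2)
  side <- if (up[1]) "I" else "O"
  for (h in seq_len(n)) {
    if (spec$loop_length > 0) {
      seq_chars <- c(seq_chars, sample_aa(spec$loop_length, LOOP_FREQ))
      topo_chars <- c(topo_chars, rep(side, spec$loop_length))
    }
    helix_range[h, ] <- c(length(seq_chars) + 1L, length(seq_chars) + len)
    seq_chars <- c(seq_chars, sample_aa(len, TM_HELIX_FREQ))
    topo_chars <- c(topo_chars, rep("H", len))
    side <- if (side == "I") "O" else "I"
  }
  if (spec$loop_length > 0) {
    seq_chars <- c(seq_chars, sample_aa(spec$loop_length, LOOP_FREQ))
    topo_chars <- c(topo_chars, rep(side, spec$loop_length))
  }

  ## coordinates
  phases <- runif(n, 0, 2 * pi)
  tilt <- spec$crossing_angle * pi / 180
  coords <- list()
  for (h in seq_len(n)) {
    t <- seq_len(len)
    theta <- phases[h] + (t - 1) * spec$twist_per_residue * pi / 180
    z <- ((t - 1) - (len - 1) / 2) * spec$rise_per_residue
    if (!up[h]) z <- -z
    ca <- cbind(spec$ca_radius * cos(theta), spec$ca_radius * sin(theta), z)
    nrm <- cbind(cos(theta), sin(theta), 0)
    cb <- ca + 1.53 * nrm
    a <- if (h %% 2 == 0) tilt / 2 else -tilt / 2
    rot <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
    ca <- ca %*% rot; cb <- cb %*% rot
    ca[, 1] <- ca[, 1] + centers[h, 1]; ca[, 2] <- ca[, 2] + centers[h, 2]
    cb[, 1] <- cb[, 1] + centers[h, 1]; cb[, 2] <- cb[, 2] + centers[h, 2]
    sp <- helix_range[h, 1]:helix_range[h, 2]
    coords[[h]] <- tibble(
      seqpos = rep(sp, 2),
      resname = rep(bio3d::aa123(seq_chars[sp]), 2),
      atom = rep(c("CA", "CB"), each = len),
      element = "C",
      x = c(ca[, 1], cb[, 1]), y = c(ca[, 2], cb[, 2]),
      z = c(ca[, 3], cb[, 3]))
  }

  protein <- parse_topology(paste0(seq_chars, collapse = ""),
                            paste0(topo_chars, collapse = ""), chain_id)
  protein$coords <- dplyr::arrange(dplyr::bind_rows(coords),
                                   .data$seqpos, .data$atom)
  list(protein = protein,
       contact_maps = list(DEF1 = label_contacts(protein, "DEF1"),
                           DEF2 = label_contacts(protein, "DEF2")),
       spec = spec)
}

#' Specification of an alignment with planted covarying columns
#'
#' Rows are drawn i.i.d. from a background residue distribution; for each
#' planted column pair, a row's two residues are instead drawn jointly from
#' a small paired-state table with probability `coupling`, which creates a
#' coevolution signal of tunable strength. Gaps are inserted uniformly at
#' random in non-query rows.
#'
#' @param n_cols Alignment width.
#' @param n_rows Number of generated rows (the query row is added on top).
#' @param planted_pairs Tibble/data frame with columns `col_i`, `col_j`,
#'   `coupling` (coupling in `(0, 1]`).
#' @param background Length-20 residue frequency vector (default uniform).
#' @param gap_rate Per-cell gap probability in non-query rows.
#' @param n_paired_states Size of each planted pair's joint state table.
#' @param seed Integer seed.
#' @return A `tm_msa_spec` list.
#' @export
planted_msa_spec <- function(n_cols, n_rows = 200, planted_pairs = NULL,
                             background = NULL, gap_rate = 0,
                             n_paired_states = 3, seed = 1) {
  background <- background %||% setNames(rep(1 / 20, 20), AA_ORDER)
  stopifnot(length(background) == 20, all(background >= 0),
            gap_rate >= 0, gap_rate < 1, n_rows >= 1, n_cols >= 1)
  if (!is.null(planted_pairs)) {
    planted_pairs <- as_tibble(planted_pairs)
    stopifnot(all(c("col_i", "col_j", "coupling") %in% names(planted_pairs)))
    if (any(planted_pairs$coupling <= 0 | planted_pairs$coupling > 1))
      abort("coupling must lie in (0, 1]")
    if (anyDuplicated(planted_pairs[, c("col_i", "col_j")]))
      abort("planted pairs must be distinct")
  }
  structure(list(n_cols = n_cols, n_rows = n_rows,
                 planted_pairs = planted_pairs,
                 background = background / sum(background),
                 gap_rate = gap_rate, n_paired_states = n_paired_states,
                 seed = seed),
            class = "tm_msa_spec")
}

#' Generate an alignment with planted covariation
#'
#' @param spec A [planted_msa_spec()].
#' @return A `tm_alignment` whose first row is the query -- the column-wise
#'   modal (gap-free) sequence of the generated rows.
#' @export
make_msa <- function(spec) {
  set.seed(spec$seed)
  m <- matrix(sample_aa(spec$n_rows * spec$n_cols, spec$background),
              nrow = spec$n_rows)
  pp <- spec$planted_pairs
  if (!is.null(pp) && nrow(pp) > 0) {
    for (p in seq_len(nrow(pp))) {
      ## joint state table: n_paired_states (a, b) residue pairs
      st_a <- sample_aa(spec$n_paired_states, spec$background)
      st_b <- sample_aa(spec$n_paired_states, spec$background)
      coupled <- runif(spec$n_rows) < pp$coupling[p]
      k <- sample.int(spec$n_paired_states, sum(coupled), replace = TRUE)
      m[coupled, pp$col_i[p]] <- st_a[k]
      m[coupled, pp$col_j[p]] <- st_b[k]
    }
  }
  query <- apply(m, 2, function(col) {
    tb <- table(factor(col, levels = AA_ORDER))
    AA_ORDER[which.max(tb)]
  })
  if (spec$gap_rate > 0) {
    mask <- matrix(runif(length(m)) < spec$gap_rate, nrow = nrow(m))
    m[mask] <- "-"
  }
  new_alignment(rbind(query, m),
                ids = c("query", paste0("row", seq_len(spec$n_rows))))
}

#' Write a synthetic multi-chain study to disk
#'
#' Generates `n_chains` helix bundles with per-chain randomized geometry,
#' plants covarying alignment columns at (a subset of) the true DEF2
#' contact positions so that the coevolution signal is informative about
#' contacts, sets each chain's sequence to its alignment's query row, and
#' writes sequence FASTA, topology text, aligned-FASTA MSA and PDB files
#' plus a manifest TSV consumable end to end.
#'
#' @param n_chains Number of chains.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; every chain derives its own seeds from
#'   it, so regeneration is byte-identical.
#' @param n_rows Alignment rows per chain.
#' @param coupling Coupling strength of planted pairs.
#' @param gap_rate Gap rate in non-query alignment rows.
#' @param n_planted Maximum planted pairs per chain.
#' @param n_helices_range,helix_length_range,axis_distance_range Per-chain
#'   geometry ranges sampled uniformly.
#' @return The manifest as a tibble (invisibly); the manifest file is
#'   `file.path(out_dir, "manifest.tsv")`.
#' @export
make_study <- function(n_chains, out_dir, seed = 1, n_rows = 120,
                       coupling = 0.9, gap_rate = 0.05, n_planted = 12,
                       n_helices_range = c(4, 5),
                       helix_length_range = c(11, 13),
                       axis_distance_range = c(10.0, 10.8)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (c in seq_len(n_chains)) {
    ch_seed <- seed + 7919L * c
    set.seed(ch_seed)
    bs <- bundle_spec(
      n_helices = sample(n_helices_range[1]:n_helices_range[2], 1),
      helix_length = sample(helix_length_range[1]:helix_length_range[2], 1),
      axis_distance = runif(1, axis_distance_range[1], axis_distance_range[2]),
      seed = ch_seed + 1L)
    id <- sprintf("syn%03d", c)
    bundle <- make_bundle(bs, chain_id = id)
    protein <- bundle$protein

    ## plant covariation at the closest true DEF2 contacts
    cts <- dplyr::arrange(bundle$contact_maps$DEF2$contacts, .data$distance)
    n_pl <- min(n_planted, nrow(cts))
    planted <- if (n_pl > 0)
      tibble(col_i = cts$seqpos_i[seq_len(n_pl)],
             col_j = cts$seqpos_j[seq_len(n_pl)],
             coupling = coupling)
    else NULL
    msa <- make_msa(planted_msa_spec(
      n_cols = nchar(protein$sequence), n_rows = n_rows,
      planted_pairs = planted, background = TM_HELIX_FREQ + 1e-3,
      gap_rate = gap_rate, seed = ch_seed + 2L))

    ## the chain's sequence is the alignment query; geometry is unchanged
    newseq <- paste0(msa$mat[1, ], collapse = "")
    protein$sequence <- newseq
    seq1 <- strsplit(newseq, "")[[1]]
    protein$coords$resname <- bio3d::aa123(seq1[protein$coords$seqpos])

    seq_file <- file.path(out_dir, paste0(id, ".fasta"))
    topo_file <- file.path(out_dir, paste0(id, ".topo"))
    msa_file <- file.path(out_dir, paste0(id, "_msa.fasta"))
    pdb_file <- file.path(out_dir, paste0(id, ".pdb"))
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(setNames(newseq, id)), seq_file)
    writeLines(protein$topology, topo_file)
    write_msa(msa, msa_file)
    co <- protein$coords
    bio3d::write.pdb(file = pdb_file,
                     xyz = as.numeric(t(as.matrix(co[, c("x", "y", "z")]))),
                     resno = co$seqpos, resid = co$resname,
                     eleno = seq_len(nrow(co)), elety = co$atom,
                     chain = rep("A", nrow(co)))
    rows[[c]] <- tibble(chain_id = id,
                        sequence_file = basename(seq_file),
                        topology_file = basename(topo_file),
                        msa_file = basename(msa_file),
                        pssm_file = "",
                        structure_file = basename(pdb_file))
  }
  manifest <- dplyr::bind_rows(rows)
  write.table(manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a study manifest
#' @param path Path to a tab-separated manifest with columns `chain_id`,
#'   `sequence_file`, `topology_file`, `msa_file`, `pssm_file` (optional),
#'   `structure_file` (optional); file paths are relative to the manifest.
#' @return Tibble of the manifest rows with paths resolved.
#' @export
read_manifest <- function(path) {
  m <- as_tibble(read.delim(path, sep = "\t", colClasses = "character"))
  need <- c("chain_id", "sequence_file", "topology_file", "msa_file")
  if (!all(need %in% names(m)))
    abort(paste("manifest must have columns:", paste(need, collapse = ", ")))
  base <- dirname(path)
  for (col in setdiff(names(m), "chain_id"))
    m[[col]] <- ifelse(is.na(m[[col]]) | m[[col]] == "", "",
                       file.path(base, m[[col]]))
  m
}

#' Read a plain-text or FASTA-like topology file
#' @param path File whose non-header lines concatenate to the topology
#'   string.
#' @return The topology string.
#' @export
read_topology_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^>", lines)])
  paste0(lines[lines != ""], collapse = "")
}

#' Run the per-chain pipeline from files to a candidate-pair dataset
#'
#' Reads one manifest row (or equivalent paths), builds the protein record,
#' filters the alignment, computes the coevolution matrices and
#' conservation profile, obtains the evolutionary profile (PSI-BLAST PSSM
#' when given, alignment-derived otherwise), labels contacts when a
#' structure is available, and assembles the candidate-pair dataset.
#'
#' @param chain_id Chain identifier.
#' @param sequence_file,topology_file,msa_file Input paths.
#' @param pssm_file,structure_file Optional input paths (`""` to skip).
#' @param methods Coevolution methods for the feature set.
#' @return A list: `protein`, `pairs` (`tm_pairs`), `contact_maps` (named
#'   list, or `NULL` without structure), `filtered`, `matrices`, `cons`.
#' @export
prepare_chain <- function(chain_id, sequence_file, topology_file, msa_file,
                          pssm_file = "", structure_file = "",
                          methods = c("MIc", "OMES", "McBASC")) {
  seqs <- Biostrings::readBStringSet(sequence_file)
  sequence <- toupper(as.character(seqs[[1]]))
  topology <- read_topology_file(topology_file)
  protein <- parse_topology(sequence, topology, chain_id)
  aln <- read_msa(msa_file)
  profile <- if (nzchar(pssm_file)) read_pssm_ascii(pssm_file)
             else profile_from_msa(aln)
  filtered <- filter_msa(aln, protein)
  matrices <- coevolution_matrices(filtered, methods = methods)
  cons <- conservation(filtered)
  contact_maps <- NULL
  if (nzchar(structure_file)) {
    protein <- read_structure(protein, structure_file, chain_id = "A")
    contact_maps <- list(DEF1 = label_contacts(protein, "DEF1"),
                         DEF2 = label_contacts(protein, "DEF2"))
  }
  pairs <- build_pair_dataset(protein, profile, matrices, cons, contact_maps)
  list(protein = protein, pairs = pairs, contact_maps = contact_maps,
       filtered = filtered, matrices = matrices, cons = cons)
}

#' Load a whole study from its manifest
#'
#' @param manifest_path Path to a manifest TSV.
#' @param methods Coevolution methods for the feature set.
#' @return A list: `datasets` (named list of `tm_pairs`), `contact_maps`
#'   (list with `DEF1` and `DEF2` named lists), `proteins`.
#' @export
load_study <- function(manifest_path, methods = c("MIc", "OMES", "McBASC")) {
  m <- read_manifest(manifest_path)
  chains <- lapply(seq_len(nrow(m)), function(r)
    prepare_chain(m$chain_id[r], m$sequence_file[r], m$topology_file[r],
                  m$msa_file[r],
                  pssm_file = if ("pssm_file" %in% names(m)) m$pssm_file[r] else "",
                  structure_file = if ("structure_file" %in% names(m))
                    m$structure_file[r] else "",
                  methods = methods))
  names(chains) <- m$chain_id
  list(
    datasets = lapply(chains, `[[`, "pairs"),
    contact_maps = list(
      DEF1 = lapply(chains, function(x) x$contact_maps$DEF1),
      DEF2 = lapply(chains, function(x) x$contact_maps$DEF2)),
    proteins = lapply(chains, `[[`, "protein"))
}
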