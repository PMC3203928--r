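#' Build a transmembrane protein record from sequence and topology
#'
#' Pairs a one-letter amino-acid sequence with a per-residue topology string
#' over the alphabet `H` (membrane-spanning helix), `I` (inside/cytoplasmic
#' loop), `O` (outside/extracellular loop) and `U` (unknown), and enumerates
#' the transmembrane helices as the maximal runs of `H`.
#'
#' Each helix records the flanking topology label on its N-terminal side
#' (`n_term_side`): the nearest non-`H`, non-`U` character before the helix,
#' or `"unknown"` when none exists. This orientation drives the
#' cytoplasm-to-extracellular indexing used by the feature encodings.
#'
#' @param sequence One-letter amino-acid sequence (single string).
#' @param topology Topology string of the same length over `{H,I,O,U}`.
#' @param chain_id Identifier attached to the record.
#' @return A `tm_protein` object: a list with `chain_id`, `sequence`,
#'   `topology`, a `helices` tibble (`helix_index`, `start`, `end`, `length`,
#'   `n_term_side`) and a `coords` slot (`NULL` until a structure is
#'   attached with [read_structure()]).
#' @examples
#' p <- parse_topology("MAGLVVILAAGLWLMFAK", "IIHHHHHHHOOHHHHHHI")
#' p$helices
#' @export
parse_topology <- function(sequence, topology, chain_id = "chain") {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(topology), length(topology) == 1L)
  if (nchar(sequence) == 0L || nchar(topology) == 0L)
    abort("sequence and topology must be non-empty")
  if (nchar(sequence) != nchar(topology))
    abort(sprintf(
      "topology length (%d) does not match sequence length (%d)",
      nchar(topology), nchar(sequence)))
  topo <- strsplit(topology, "")[[1]]
  bad <- which(!topo %in% c("H", "I", "O", "U"))
  if (length(bad) > 0L)
    abort(sprintf("illegal topology character '%s' at position %d",
                  topo[bad[1]], bad[1]))

  r <- rle(topo == "H")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  helices <- tibble(
    helix_index = seq_len(sum(keep)),
    start = starts[keep],
    end = ends[keep],
    length = r$lengths[keep]
  )
  helices$n_term_side <- vapply(helices$start, function(s) {
    before <- topo[seq_len(s - 1L)]
    before <- before[!before %in% c("H", "U")]
    if (length(before) == 0L) return("unknown")
    if (before[length(before)] == "I") "inside" else "outside"
  }, character(1))

  structure(
    list(chain_id = chain_id, sequence = toupper(sequence),
         topology = topology, helices = helices, coords = NULL),
    class = "tm_protein")
}

#' @export
print.tm_protein <- function(x, ...) {
  cat(sprintf("<tm_protein> %s: %d residues, %d TM helices%s\n",
              x$chain_id, nchar(x$sequence), nrow(x$helices),
              if (is.null(x$coords)) "" else ", with coordinates"))
  if (nrow(x$helices)) print(x$helices)
  invisible(x)
}

## total TM length L: sum of helix lengths
chain_L <- function(protein) sum(protein$helices$length)

## per-position logical: is this sequence position inside a TM helix
tm_mask <- function(protein) strsplit(protein$topology, "")[[1]] == "H"

#' Read an aligned FASTA multiple sequence alignment
#'
#' The first record is taken as the query. `.` and `-` are both treated as
#' gap characters and all residues are uppercased. A `column_map` from
#' alignment columns to query sequence positions is built from the query row.
#'
#' @param path Path to an aligned FASTA file.
#' @return A `tm_alignment`: list with `mat` (character matrix, rows =
#'   sequences), `ids`, and `column_map` (integer vector, one entry per
#'   alignment column; `NA` where the query has a gap).
#' @export
read_msa <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0("cannot read MSA: ",
                                                   conditionMessage(e))))
  if (length(set) == 0L) abort("empty MSA file")
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1L)
    abort(sprintf("ragged alignment: row widths %s",
                  paste(unique(w), collapse = ", ")))
  rows <- toupper(as.character(set))
  mat <- do.call(rbind, strsplit(rows, ""))
  mat[mat == "."] <- "-"
  new_alignment(mat, names(set))
}

#' Build an alignment from character strings
#'
#' Programmatic counterpart of [read_msa()]: takes already-aligned sequences
#' (query first), uppercases them and treats `.` like `-`.
#'
#' @param rows Character vector of equal-length aligned sequences.
#' @param ids Optional sequence identifiers.
#' @return A `tm_alignment`.
#' @export
alignment_matrix <- function(rows, ids = NULL) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  if (length(unique(nchar(rows))) != 1L) abort("ragged alignment rows")
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  mat[mat == "."] <- "-"
  new_alignment(mat, ids)
}

new_alignment <- function(mat, ids = NULL) {
  ids <- ids %||% rownames(mat) %||% paste0("seq", seq_len(nrow(mat)))
  dimnames(mat) <- NULL
  query_nongap <- mat[1, ] != "-"
  column_map <- rep(NA_integer_, ncol(mat))
  column_map[query_nongap] <- seq_len(sum(query_nongap))
  structure(list(mat = mat, ids = ids, column_map = column_map),
            class = "tm_alignment")
}

#' @export
print.tm_alignment <- function(x, ...) {
  cat(sprintf("<tm_alignment> %d sequences x %d columns (%d query positions)\n",
              nrow(x$mat), ncol(x$mat), sum(!is.na(x$column_map))))
  invisible(x)
}

#' Write an alignment back to aligned FASTA
#' @param aln A `tm_alignment`.
#' @param path Output path.
#' @export
write_msa <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste0, collapse = "")
  set <- Biostrings::BStringSet(setNames(seqs, aln$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the classic PSI-BLAST `-Q` ASCII dialect: header lines followed by
#' one row per query residue carrying 20 log-odds columns and 20 weighted
#' observed-percentage columns. By default the profile is built from the
#' percentage block divided by 100, giving per-position amino-acid
#' frequencies; set `use_log_odds = TRUE` to keep the log-odds block instead.
#'
#' @param path Path to the ASCII PSSM.
#' @param use_log_odds Use the log-odds block rather than frequencies.
#' @return A `tm_profile`: numeric matrix with one row per query residue and
#'   20 columns in the canonical order `ACDEFGHIKLMNPQRSTVWY`, with
#'   attributes `source` and `query` (the residue letters of the parsed rows).
#' @export
read_pssm_ascii <- function(path, use_log_odds = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort("empty PSSM file")
  ## column order from the header line (PSI-BLAST prints its own residue
  ## order, classically ARNDCQEGHILKMFPSTWYV, once for each block)
  col_order <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) >= 40L && all(grepl("^[A-Za-z]$", tok))) {
      col_order <- toupper(tok[21:40])
      break
    }
    if (length(tok) >= 20L && length(tok) < 40L &&
        all(grepl("^[A-Za-z]$", tok))) {
      col_order <- toupper(tok[1:20])
      break
    }
  }
  rows <- list(); res <- character(); last_good <- 0L
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(tok) < 2L) next
    if (!grepl("^[0-9]+$", tok[1]) || !grepl("^[A-Za-z]$", tok[2])) next
    nums <- suppressWarnings(as.numeric(tok[-(1:2)]))
    ## trailing information-content / weight columns are optional
    if (length(nums) >= 40L && !anyNA(nums[1:40])) {
      rows[[length(rows) + 1L]] <- nums[1:40]
      res <- c(res, toupper(tok[2]))
      last_good <- k
    } else {
      abort(sprintf(
        "PSSM line %d: expected 40 numeric fields, found %d (last good line %d)",
        k, sum(!is.na(nums)), last_good))
    }
  }
  if (length(rows) == 0L) abort("no PSSM data rows found")
  m <- do.call(rbind, rows)
  prof <- if (use_log_odds) m[, 1:20, drop = FALSE] else m[, 21:40, drop = FALSE] / 100
  colnames(prof) <- col_order
  prof <- prof[, AA_ORDER, drop = FALSE]  # canonical residue order
  structure(prof, source = if (use_log_odds) "psiblast_logodds" else "psiblast_ascii",
            query = res, class = c("tm_profile", "matrix", "array"))
}

#' Derive an evolutionary profile from an alignment
#'
#' Fallback when no PSI-BLAST profile is available: for each query position
#' the relative frequency of the 20 amino acids over non-gap rows of the
#' corresponding alignment column. Non-standard residue codes (B, Z, X, U,
#' O) count as gaps. A column with no standard residue gets the uniform
#' profile 1/20.
#'
#' @param aln A `tm_alignment` whose first row is the query.
#' @return A `tm_profile` matrix (query length x 20), rows summing to 1.
#' @export
profile_from_msa <- function(aln) {
  qcols <- which(!is.na(aln$column_map))
  prof <- matrix(0, nrow = length(qcols), ncol = 20,
                 dimnames = list(NULL, AA_ORDER))
  for (k in seq_along(qcols)) {
    col <- aln$mat[, qcols[k]]
    col <- col[!is_gaplike(col)]
    if (length(col) == 0L) {
      prof[k, ] <- 1 / 20
    } else {
      cnt <- tabulate(aa_code(col), nbins = 20)
      prof[k, ] <- cnt / sum(cnt)
    }
  }
  structure(prof, source = "msa_derived",
            query = substring(gsub("-", "", paste0(aln$mat[1, ], collapse = "")),
                              seq_len(nrow(prof)), seq_len(nrow(prof))),
            class = c("tm_profile", "matrix", "array"))
}

#' Attach 3-D coordinates from a PDB file to a protein record
#'
#' Reads `ATOM` records for one chain, keeps heavy atoms only (element not
#' H/D; highest-occupancy alternate location), and maps structure residues to
#' sequence positions. When residue numbers are consistent with the sequence
#' they are used directly; otherwise residues are mapped by serial order.
#' Either way residue identities are checked against the sequence and more
#' than 5% mismatches abort. Sequence positions without coordinates are
#' simply left coordinate-less.
#'
#' @param protein A `tm_protein`.
#' @param path Path to a PDB file.
#' @param chain_id Chain identifier inside the PDB file.
#' @return The protein with a `coords` tibble: `seqpos`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`.
#' @export
read_structure <- function(protein, path, chain_id = protein$chain_id) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0L)
    abort(sprintf("chain '%s' not found in %s", chain_id, path))
  elem <- at$elesy
  noelem <- is.na(elem) | elem == ""
  elem[noelem] <- substr(gsub("[0-9]", "", at$elety[noelem]), 1, 1)
  at <- at[!(toupper(elem) %in% c("H", "D")), , drop = FALSE]
  elem <- elem[!(toupper(elem) %in% c("H", "D"))]
  ## alternate locations: keep the highest-occupancy copy of each atom
  if (any(!at$alt %in% c("", NA))) {
    key <- paste(at$resno, at$elety)
    ord <- order(key, -replace(at$o, is.na(at$o), 1))
    at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  }

  resno <- at$resno
  uniq <- unique(resno)
  L <- nchar(protein$sequence)
  seq1 <- strsplit(protein$sequence, "")[[1]]
  one <- suppressWarnings(bio3d::aa321(at$resid[match(uniq, resno)]))

  map_ok <- function(seqpos) {
    ok <- !is.na(seqpos) & seqpos >= 1 & seqpos <= L
    mism <- which(ok & !is.na(one) & one != "X" & one != seq1[seqpos])
    list(ok = all(ok), mism = mism)
  }
  seqpos_direct <- uniq
  direct <- map_ok(seqpos_direct)
  if (direct$ok && length(direct$mism) / length(uniq) <= 0.05) {
    seqpos <- seqpos_direct
  } else {
    seqpos <- seq_along(uniq)  # serial order
    serial <- map_ok(seqpos)
    if (!serial$ok || length(serial$mism) / length(uniq) > 0.05)
      abort(sprintf(
        "cannot map structure residues to sequence; mismatched positions: %s",
        paste(head(uniq[union(direct$mism, serial$mism)], 10), collapse = ", ")))
  }

  protein$coords <- tibble(
    seqpos = seqpos[match(resno, uniq)],
    resname = at$resid,
    atom = at$elety,
    element = toupper(elem),
    x = at$x, y = at$y, z = at$z)
  protein
}
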