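#' Residue-contact definitions
#'
#' Two contact definitions between residues of different TM helices:
#' `DEF1` — the minimal distance between any heavy atoms (backbone or side
#' chain) of the two residues is less than 5.5 Angstrom; `DEF2` — the
#' C-beta atoms (C-alpha for glycine) are less than 8 Angstrom apart. Both
#' comparisons are strict.
#'
#' @param name `"DEF1"` or `"DEF2"`.
#' @param cutoff Optional override of the distance cutoff in Angstrom.
#' @return A `tm_contact_definition` list: `name`, `atom_rule`, `cutoff`.
#' @export
contact_definition <- function(name = c("DEF1", "DEF2"), cutoff = NULL) {
  name <- match.arg(name)
  cutoff <- cutoff %||% if (name == "DEF1") 5.5 else 8.0
  stopifnot(cutoff > 0)
  structure(list(name = name,
                 atom_rule = if (name == "DEF1") "min_heavy_atom" else "cbeta_or_ca_gly",
                 cutoff = cutoff),
            class = "tm_contact_definition")
}

#' Label inter-helix residue contacts from 3-D coordinates
#'
#' Enumerates all residue pairs between different TM helices (topology `H`
#' positions only) and labels each pair as contact/non-contact under a
#' contact definition. Under `DEF1` the minimum over all heavy-atom pairs of
#' the two residues is used; under `DEF2` the C-beta distance (C-alpha for
#' glycine; for other residues a missing C-beta falls back to C-alpha with a
#' warning, and residues with neither atom are skipped and recorded).
#'
#' @param protein A `tm_protein` with coordinates attached.
#' @param definition A [contact_definition()] (or `"DEF1"`/`"DEF2"`).
#' @return A `tm_contact_map`: `definition`, `contacts` tibble (`helix_a`,
#'   `helix_b`, `seqpos_i`, `seqpos_j`, `distance`), `interacting` tibble of
#'   helix pairs with at least one contact, `skipped` tibble of residues
#'   without usable atoms, and `n_helices`.
#' @export
label_contacts <- function(protein, definition = contact_definition("DEF1")) {
  if (is.character(definition)) definition <- contact_definition(definition)
  if (is.null(protein$coords)) abort("protein has no coordinates")
  hx <- protein$helices
  if (nrow(hx) < 2L)
    return(new_contact_map(definition, empty_contacts(), protein))

  co <- protein$coords
  seq1 <- strsplit(protein$sequence, "")[[1]]
  skipped <- integer(0)

  ## per-residue coordinate matrix for the definition's atom rule
  res_atoms <- function(seqpos) {
    sub <- co[co$seqpos == seqpos, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    if (definition$atom_rule == "min_heavy_atom")
      return(as.matrix(sub[, c("x", "y", "z")]))
    want <- if (seq1[seqpos] == "G") "CA" else "CB"
    hit <- sub[sub$atom == want, , drop = FALSE]
    if (nrow(hit) == 0L && want == "CB") {
      hit <- sub[sub$atom == "CA", , drop = FALSE]
      if (nrow(hit) > 0L)
        warn(sprintf("residue %d lacks CB; falling back to CA", seqpos))
    }
    if (nrow(hit) == 0L) return(NULL)
    as.matrix(hit[1, c("x", "y", "z"), drop = FALSE])
  }

  atom_cache <- lapply(seq_len(nchar(protein$sequence)), function(i) NULL)
  tm_res <- unlist(lapply(seq_len(nrow(hx)), function(h) hx$start[h]:hx$end[h]))
  for (i in tm_res) {
    a <- res_atoms(i)
    if (is.null(a)) skipped <- c(skipped, i) else atom_cache[[i]] <- a
  }

  rows <- list()
  for (a in seq_len(nrow(hx) - 1L)) {
    for (b in (a + 1L):nrow(hx)) {
      for (i in hx$start[a]:hx$end[a]) {
        ai <- atom_cache[[i]]
        if (is.null(ai)) next
        for (j in hx$start[b]:hx$end[b]) {
          aj <- atom_cache[[j]]
          if (is.null(aj)) next
          d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)
          dmin <- sqrt(max(min(d2), 0))
          if (dmin < definition$cutoff)
            rows[[length(rows) + 1L]] <- tibble(
              helix_a = a, helix_b = b, seqpos_i = i, seqpos_j = j,
              distance = dmin)
        }
      }
    }
  }
  contacts <- if (length(rows)) dplyr::bind_rows(rows) else empty_contacts()
  cm <- new_contact_map(definition, contacts, protein)
  cm$skipped <- tibble(seqpos = skipped)
  cm
}

empty_contacts <- function() {
  tibble(helix_a = integer(), helix_b = integer(),
         seqpos_i = integer(), seqpos_j = integer(), distance = numeric())
}

new_contact_map <- function(definition, contacts, protein) {
  structure(list(
    definition = definition,
    contacts = contacts,
    interacting = dplyr::distinct(contacts[, c("helix_a", "helix_b")]),
    skipped = tibble(seqpos = integer(0)),
    n_helices = nrow(protein$helices),
    chain_id = protein$chain_id),
    class = "tm_contact_map")
}

#' @export
print.tm_contact_map <- function(x, ...) {
  cat(sprintf("<tm_contact_map> %s (<%g A): %d contacts, %d interacting helix pairs\n",
              x$definition$name, x$definition$cutoff,
              nrow(x$contacts), nrow(x$interacting)))
  invisible(x)
}

#' Interacting helix pairs of a contact map
#'
#' Two TM helices interact when they share at least one residue contact.
#'
#' @param cm A `tm_contact_map`.
#' @return Tibble with columns `helix_a`, `helix_b` (`helix_a < helix_b`).
#' @export
interacting_pairs <- function(cm) cm$interacting

#' Export a contact map as a plain table
#' @param cm A `tm_contact_map`.
#' @return Tibble: `helix_a`, `helix_b`, `seqpos_i`, `seqpos_j`, `distance`,
#'   `definition`.
#' @export
contact_map_tbl <- function(cm) {
  dplyr::mutate(cm$contacts, definition = cm$definition$name)
}
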