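## Per-pair feature encoding: two 9-residue profile windows (360), windowed
## coevolution scores along the helix-helix diagonal (27), two 9-residue
## conservation windows (18), the membrane-normal relative distance, the
## sequence separation and the chain's TM helix count -- 408 components.

OFFSET_LAB <- c("m4", "m3", "m2", "m1", "c0", "p1", "p2", "p3", "p4")

## +1 when within-helix position 1 is the N-terminal residue (cytoplasmic
## N-side), -1 when it is the C-terminal residue. Helices are indexed from
## the cytoplasm to the extracellular side; "inside" is taken as cytoplasmic.
helix_direction <- function(protein, helix_index, warn_unknown = TRUE) {
  side <- protein$helices$n_term_side[helix_index]
  if (side == "inside") return(1L)
  if (side == "outside") return(-1L)
  if (warn_unknown)
    warn(sprintf("helix %d has unknown orientation; using N-to-C direction",
                 helix_index))
  1L
}

## within-helix position p (1..l) counted along the cytoplasm->extracellular
## direction of the helix containing seqpos
helix_position <- function(protein, seqpos, helix_index, warn_unknown = TRUE) {
  hx <- protein$helices[helix_index, ]
  if (helix_direction(protein, helix_index, warn_unknown) == 1L)
    seqpos - hx$start + 1L
  else
    hx$end - seqpos + 1L
}

#' Sliding-window profile encoding of one residue
#'
#' Concatenates the 20-component profile rows of the nine sequence positions
#' centred on `seqpos`; positions beyond either terminus contribute
#' 20-component zero vectors.
#'
#' @param profile A `tm_profile` matrix (query length x 20).
#' @param seqpos Sequence position (1-based, within the query).
#' @return Numeric vector of length 180.
#' @export
encode_profile_window <- function(profile, seqpos) {
  L <- nrow(profile)
  if (seqpos < 1L || seqpos > L) abort("seqpos outside the sequence")
  out <- numeric(180)
  for (k in -4:4) {
    p <- seqpos + k
    if (p >= 1L && p <= L) out[(k + 4L) * 20L + 1:20] <- profile[p, ]
  }
  names(out) <- paste0(rep(OFFSET_LAB, each = 20), "_", rep(AA_ORDER, 9))
  out
}

#' Windowed coevolution encoding of a residue pair
#'
#' For each coevolution method, the standardized scores `S(i + k, j + k)` at
#' diagonal offsets `k = -4..+4`, where the positive direction along each
#' helix runs from the cytoplasm to the extracellular side (derived from the
#' helix's `n_term_side`; unknown orientation falls back to N-to-C with a
#' warning). Offsets that leave either helix contribute 0.
#'
#' @param matrices List of `tm_coevolution` objects (one per method) from
#'   [coevolution_matrices()].
#' @param protein The `tm_protein`.
#' @param i,j Sequence positions in two different TM helices.
#' @return Numeric vector of length `9 * length(matrices)` (27 for the
#'   default three methods), method-major.
#' @export
encode_coevolution_window <- function(matrices, protein, i, j) {
  hx <- protein$helices
  hi <- which(hx$start <= i & hx$end >= i)
  hj <- which(hx$start <= j & hx$end >= j)
  if (length(hi) != 1L || length(hj) != 1L || hi == hj)
    abort("i and j must lie in two different TM helices")
  di <- helix_direction(protein, hi)
  dj <- helix_direction(protein, hj)
  ii <- i + (-4:4) * di
  jj <- j + (-4:4) * dj
  valid <- ii >= hx$start[hi] & ii <= hx$end[hi] &
    jj >= hx$start[hj] & jj <= hx$end[hj]
  out <- unlist(lapply(matrices, function(m) {
    sp <- as.integer(rownames(m$standardized))
    v <- numeric(9)
    v[valid] <- m$standardized[cbind(match(ii[valid], sp), match(jj[valid], sp))]
    v
  }))
  names(out) <- paste0("coev_",
                       rep(vapply(matrices, `[[`, "", "method"), each = 9),
                       "_", rep(OFFSET_LAB, length(matrices)))
  out
}

#' Sliding-window conservation encoding of one residue
#'
#' Nine standardized conservation values at the sequence positions centred
#' on `seqpos`; positions outside TM segments (where conservation is not
#' defined) contribute 0.
#'
#' @param cons A `tm_conservation` tibble.
#' @param seqpos Sequence position.
#' @return Numeric vector of length 9.
#' @export
encode_conservation_window <- function(cons, seqpos) {
  idx <- match(seqpos + (-4:4), cons$seqpos)
  out <- ifelse(is.na(idx), 0, cons$standardized[idx])
  names(out) <- paste0("cons_", OFFSET_LAB)
  out
}

#' Membrane-normal relative distance of two helix residues
#'
#' For residues at within-helix positions `p1`, `p2` (counted from the
#' cytoplasm to the extracellular side) of helices with `l1`, `l2` residues,
#' the relative distance is `|p1/l1 - p2/l2|` -- a proxy for their
#' separation perpendicular to the membrane surface.
#'
#' @param p1,p2 Within-helix positions (1-based).
#' @param l1,l2 Helix lengths.
#' @return Value in `[0, 1)`.
#' @export
relative_distance <- function(p1, l1, p2, l2) {
  if (any(p1 < 1 | p1 > l1) || any(p2 < 1 | p2 > l2))
    abort("within-helix positions must satisfy 1 <= p <= l")
  abs(p1 / l1 - p2 / l2)
}

#' Assemble the candidate-pair dataset of one chain
#'
#' Enumerates every residue pair spanning two different TM helices (in
#' canonical order: `helix_a < helix_b`, `i` from `helix_a`) and attaches
#' the 408-component feature vector: 360 profile components, 27 windowed
#' coevolution components, 18 conservation components, the relative
#' distance, the sequence separation and the chain's helix count. When
#' contact maps are supplied the corresponding contact labels are attached.
#'
#' @param protein A `tm_protein` (>= 2 helices for a non-empty result).
#' @param profile A `tm_profile` for the chain.
#' @param matrices Coevolution matrices from [coevolution_matrices()].
#' @param cons A `tm_conservation` tibble.
#' @param contact_maps Optional named list of `tm_contact_map`s (e.g.
#'   `list(DEF1 = ..., DEF2 = ...)`); adds logical `label_<name>` columns.
#' @return A `tm_pairs` tibble: `chain_id`, `helix_a`, `helix_b`,
#'   `seqpos_i`, `seqpos_j`, a 408-column `features` matrix column, and any
#'   label columns. Attributes `L` (total TM length), `n_helices`.
#' @export
build_pair_dataset <- function(protein, profile, matrices, cons,
                               contact_maps = NULL) {
  hx <- protein$helices
  if (nrow(profile) != nchar(protein$sequence))
    abort("profile rows must equal sequence length")
  if (nrow(hx) < 2L) {
    warn("fewer than 2 TM helices; no candidate pairs")
    return(new_tm_pairs(tibble(chain_id = character(), helix_a = integer(),
                               helix_b = integer(), seqpos_i = integer(),
                               seqpos_j = integer()),
                        matrix(numeric(), 0, 408), protein, contact_maps))
  }

  ## silence the per-call unknown-orientation warning; warn once here
  if (any(hx$n_term_side == "unknown"))
    warn("some helices have unknown orientation; using N-to-C direction")

  tm_pos <- unlist(lapply(seq_len(nrow(hx)), function(h) hx$start[h]:hx$end[h]))
  prof_win <- lapply(setNames(tm_pos, tm_pos), encode_profile_window,
                     profile = profile)
  cons_win <- lapply(setNames(tm_pos, tm_pos), encode_conservation_window,
                     cons = cons)
  hpos <- setNames(integer(length(tm_pos)), tm_pos)
  hof <- setNames(integer(length(tm_pos)), tm_pos)
  for (h in seq_len(nrow(hx))) {
    rng <- hx$start[h]:hx$end[h]
    hof[as.character(rng)] <- h
    hpos[as.character(rng)] <- vapply(rng, function(s)
      helix_position(protein, s, h, warn_unknown = FALSE), integer(1))
  }

  pairs <- dplyr::bind_rows(lapply(seq_len(nrow(hx) - 1L), function(a) {
    dplyr::bind_rows(lapply((a + 1L):nrow(hx), function(b) {
      tidyr::expand_grid(seqpos_i = hx$start[a]:hx$end[a],
                         seqpos_j = hx$start[b]:hx$end[b]) |>
        dplyr::mutate(helix_a = a, helix_b = b, .before = 1)
    }))
  }))

  meth_names <- vapply(matrices, `[[`, "", "method")
  feat <- matrix(0, nrow(pairs), 408)
  withCallingHandlers(
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$seqpos_i[r]; j <- pairs$seqpos_j[r]
      a <- pairs$helix_a[r]; b <- pairs$helix_b[r]
      ci <- as.character(i); cj <- as.character(j)
      feat[r, ] <- c(
        prof_win[[ci]], prof_win[[cj]],
        encode_coevolution_window(matrices, protein, i, j),
        cons_win[[ci]], cons_win[[cj]],
        relative_distance(hpos[ci], hx$length[a], hpos[cj], hx$length[b]),
        abs(i - j),
        nrow(hx))
    },
    warning = function(w) invokeRestart("muffleWarning"))
  colnames(feat) <- c(
    paste0("prof_i_", rep(OFFSET_LAB, each = 20), "_", rep(AA_ORDER, 9)),
    paste0("prof_j_", rep(OFFSET_LAB, each = 20), "_", rep(AA_ORDER, 9)),
    paste0("coev_", rep(meth_names, each = 9), "_",
           rep(OFFSET_LAB, length(meth_names))),
    paste0("cons_i_", OFFSET_LAB), paste0("cons_j_", OFFSET_LAB),
    "rel_dist", "seq_sep", "n_helices")

  out <- dplyr::mutate(pairs, chain_id = protein$chain_id, .before = 1)
  new_tm_pairs(out, feat, protein, contact_maps)
}

new_tm_pairs <- function(meta, feat, protein, contact_maps) {
  meta$features <- feat
  if (!is.null(contact_maps)) {
    for (nm in names(contact_maps)) {
      key <- paste(contact_maps[[nm]]$contacts$seqpos_i,
                   contact_maps[[nm]]$contacts$seqpos_j)
      meta[[paste0("label_", nm)]] <-
        paste(meta$seqpos_i, meta$seqpos_j) %in% key
    }
  }
  structure(meta,
            class = c("tm_pairs", class(tibble())),
            chain_id = protein$chain_id,
            L = chain_L(protein),
            n_helices = nrow(protein$helices))
}
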