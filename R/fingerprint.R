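#' The NC-MFP fingerprint engine
#'
#' A fingerprint is a fixed-length bit string laid out as three ordered
#' feature blocks: scaffolds (in library order), scaffold-fragment connection
#' points (SFCPs: scaffold atom positions carrying a fragment), and fragments
#' (connected pieces left after removing a matched scaffold, indexed by
#' ascending molecular weight). Generation follows six steps: preprocessing,
#' scaffold matching, fragment generation, SFCP assignment, fragment
#' identification, and bit-string representation.
#'
#' SFCP positions refer to the scaffold's own canonical atom ordering and are
#' reduced by the scaffold's automorphism group to the minimal index tuple, so
#' they do not depend on the query's atom numbering.
#'
#' @name fingerprint
NULL

## ---- decomposition (steps II-IV) -------------------------------------------

# adjacency info over heavy atoms of a prepared molecule
heavy_adj <- function(m) {
  hv <- heavy_idx(m)
  bkeep <- which(m$bonds$a1 %in% hv & m$bonds$a2 %in% hv)
  list(
    hv = hv,
    b_a1 = match(m$bonds$a1[bkeep], hv),
    b_a2 = match(m$bonds$a2[bkeep], hv),
    b_order = m$bonds$order[bkeep],
    b_arom = m$bonds$aromatic[bkeep]
  )
}

# Decompose a prepared query against scaffold structures.
# scaffolds: tibble(smiles, mol). Returns
#   matched: character vector of matched scaffold smiles
#   attachments: tibble(scaffold, profile, position, fragment, mw) with one row
#     per fragment occurrence of each symmetry-distinct attachment pattern
#   mappings: named list scaffold smiles -> representative mapping (one per
#     distinct pattern; 0-based target atom indices per scaffold atom)
ncmfp_decompose <- function(prep, scaffolds) {
  tgraph <- mol_graph_heavy(prep)
  tadj <- heavy_adj(prep)
  nheavy <- length(tadj$hv)
  matched <- character(0)
  att_rows <- list()
  mappings <- list()
  frag_cache <- new.env(parent = emptyenv())

  for (si in seq_len(nrow(scaffolds))) {
    smi <- scaffolds$smiles[si]
    if (smi %in% matched) next # duplicate scaffold entry (cross-class)
    sm <- scaffolds$mol[[si]]
    pg <- mol_graph_heavy(sm)
    maps <- match_heavy(pg, tgraph)
    if (length(maps) == 0) next
    matched <- c(matched, smi)
    auts <- mol_automorphisms(sm, key = smi)

    profiles <- character(0)
    for (e in maps) {
      inside <- logical(nheavy); inside[e] <- TRUE
      # broken bonds: one end mapped, the other outside
      bx <- which(inside[tadj$b_a1] != inside[tadj$b_a2])
      if (length(bx) == 0) {
        # scaffold covers the whole heavy skeleton: scaffold-only profile
        key <- "<bare>"
        if (!key %in% profiles) {
          profiles <- c(profiles, key)
          if (is.null(mappings[[smi]])) mappings[[smi]] <- list()
          mappings[[smi]][[key]] <- tadj$hv[e] - 1L
        }
        next
      }
      # components of the unmapped remainder
      outside <- which(!inside)
      comp_of <- rep(NA_integer_, nheavy)
      okeep <- which(!inside[tadj$b_a1] & !inside[tadj$b_a2])
      gout <- igraph::graph_from_edgelist(
        cbind(match(tadj$b_a1[okeep], outside), match(tadj$b_a2[okeep], outside)),
        directed = FALSE
      )
      gout <- igraph::add_vertices(gout, max(0L, length(outside) - igraph::vcount(gout)))
      comp_of[outside] <- igraph::components(gout)$membership

      # broken-bond occurrences: scaffold position + fragment component
      occ_pos <- integer(length(bx))
      occ_comp <- integer(length(bx))
      for (k in seq_along(bx)) {
        b <- bx[k]
        t_in <- if (inside[tadj$b_a1[b]]) tadj$b_a1[b] else tadj$b_a2[b]
        t_out <- if (inside[tadj$b_a1[b]]) tadj$b_a2[b] else tadj$b_a1[b]
        occ_pos[k] <- which(e == t_in)
        occ_comp[k] <- comp_of[t_out]
      }
      # fragment per component: cut atoms + one marker per broken bond
      comp_ids <- sort(unique(occ_comp))
      frag_smi <- character(max(comp_ids))
      frag_mw <- numeric(max(comp_ids))
      for (ci in comp_ids) {
        catoms <- tadj$hv[outside[comp_of[outside] == ci]]
        cut_bonds <- bx[occ_comp == ci]
        fkey <- paste(c(sort(catoms), 0L, sort(cut_bonds)), collapse = ",")
        hit <- if (exists(fkey, envir = frag_cache, inherits = FALSE)) {
          get(fkey, envir = frag_cache, inherits = FALSE)
        } else {
          frag <- fragment_mol(prep, tadj, catoms, cut_bonds, inside)
          res <- list(smiles = frag$smiles, mw = frag$mw)
          assign(fkey, res, envir = frag_cache)
          res
        }
        frag_smi[ci] <- hit$smiles
        frag_mw[ci] <- hit$mw
      }

      # symmetry reduction: minimal profile over the automorphism group
      occ_frag <- frag_smi[occ_comp]
      best_key <- NULL; best_pos <- NULL
      for (a in auts) {
        pos2 <- a[occ_pos]
        ord <- order(pos2, occ_frag)
        key <- paste(pos2[ord] - 1L, occ_frag[ord], sep = ":", collapse = "|")
        if (is.null(best_key) || key < best_key) {
          best_key <- key; best_pos <- pos2
        }
      }
      if (!best_key %in% profiles) {
        profiles <- c(profiles, best_key)
        att_rows[[length(att_rows) + 1L]] <- tibble::tibble(
          scaffold = smi, profile = best_key,
          position = best_pos - 1L,
          fragment = occ_frag,
          mw = frag_mw[occ_comp]
        )
        if (is.null(mappings[[smi]])) mappings[[smi]] <- list()
        mappings[[smi]][[best_key]] <- tadj$hv[e] - 1L
      }
    }
  }
  attachments <- if (length(att_rows) > 0) {
    dplyr::bind_rows(att_rows)
  } else {
    tibble::tibble(
      scaffold = character(0), profile = character(0),
      position = integer(0), fragment = character(0), mw = numeric(0)
    )
  }
  list(matched = matched, attachments = attachments, mappings = mappings)
}

# build a fragment molecule: component atoms plus one '*' marker per cut bond
fragment_mol <- function(prep, tadj, catoms, cut_bonds, inside) {
  frag <- submol(prep, catoms, fix_h = FALSE)
  for (b in cut_bonds) {
    t_out <- if (inside[tadj$b_a1[b]]) tadj$b_a2[b] else tadj$b_a1[b]
    anchor <- match(tadj$hv[t_out], sort(catoms))
    frag$atoms <- tibble::add_row(frag$atoms,
      element = "*", charge = 0L, aromatic = FALSE, hcount = 0L
    )
    frag$bonds <- tibble::add_row(frag$bonds,
      a1 = anchor, a2 = nrow(frag$atoms),
      order = 1L, aromatic = FALSE
    )
  }
  smi <- canonical_form(frag)
  mw <- mol_weight(frag)
  list(smiles = if (is.na(smi)) NA_character_ else smi, mw = mw)
}

## ---- exported step operations ----------------------------------------------

#' Match dictionary scaffolds against a query (step II)
#'
#' Finds every dictionary scaffold that is a substructure of the query and
#' returns one representative atom mapping per symmetry-distinct attachment
#' pattern.
#'
#' @param q A prepared molecule with at least one ring.
#' @param dict An `ncmfp_dictionary` (or a `scaffold_library`).
#' @return A tibble with columns `scaffold` (canonical SMILES) and `mapping`
#'   (list of 0-based query atom index vectors, one entry per scaffold atom).
#' @export
match_scaffolds <- function(q, dict) {
  q <- preprocess(q)
  if (ring_count(q) < 1) {
    ncmfp_abort(
      "Fingerprints are defined only for compounds with at least one ring.",
      "ncmfp_ring_error"
    )
  }
  sc <- dict_scaffold_mols(dict)
  dec <- ncmfp_decompose(q, sc)
  rows <- list()
  for (smi in names(dec$mappings)) {
    for (key in names(dec$mappings[[smi]])) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scaffold = smi, pattern = key, mapping = list(dec$mappings[[smi]][[key]])
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(scaffold = character(0), pattern = character(0), mapping = list()))
  }
  dplyr::bind_rows(rows)
}

#' Generate fragments for one scaffold embedding (step III)
#'
#' Removes the mapped scaffold atoms from the query; every remaining connected
#' heavy-atom component becomes a fragment carrying a `*` attachment marker at
#' each cut bond. Duplicate fragments are collapsed with an occurrence count
#' and sorted by ascending molecular weight (markers weigh nothing).
#'
#' @param q A prepared molecule.
#' @param mapping 0-based query atom indices of the scaffold embedding (as
#'   returned in [match_scaffolds()]'s `mapping` column).
#' @return A tibble with columns `smiles`, `mw`, `count`.
#' @export
generate_fragments <- function(q, mapping) {
  q <- preprocess(q)
  tadj <- heavy_adj(q)
  occ <- embedding_occurrences(q, tadj, mapping)
  if (nrow(occ) == 0) {
    return(tibble::tibble(smiles = character(0), mw = numeric(0), count = integer(0)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(occ, .data$fragment, .data$mw),
    count = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$mw, .data$fragment)
  tibble::tibble(smiles = out$fragment, mw = out$mw, count = out$count)
}

#' Assign scaffold-fragment connection points (step IV)
#'
#' Reports, for each fragment occurrence of an embedding, the scaffold atom it
#' is bonded to, as a 0-based position in the scaffold's canonical atom
#' ordering, reduced over the scaffold's automorphism group to the minimal
#' index tuple (symmetric scaffolds would otherwise yield arbitrary indices).
#'
#' @param q A prepared query molecule.
#' @param scaffold The scaffold (`ncmfp_mol` or canonical SMILES).
#' @param mapping 0-based query atom indices of the embedding.
#' @return A tibble with columns `position` (0-based scaffold atom index) and
#'   `fragment` (canonical form).
#' @export
assign_sfcp <- function(q, scaffold, mapping) {
  q <- preprocess(q)
  if (is.character(scaffold)) scaffold <- scaffold_mol(scaffold)
  tadj <- heavy_adj(q)
  occ <- embedding_occurrences(q, tadj, mapping)
  if (nrow(occ) == 0) {
    return(tibble::tibble(position = integer(0), fragment = character(0)))
  }
  auts <- mol_automorphisms(scaffold)
  best_key <- NULL; best <- NULL
  for (a in auts) {
    pos2 <- a[occ$position_raw]
    ord <- order(pos2, occ$fragment)
    key <- paste(pos2[ord] - 1L, occ$fragment[ord], sep = ":", collapse = "|")
    if (is.null(best_key) || key < best_key) {
      best_key <- key
      best <- tibble::tibble(position = pos2[ord] - 1L, fragment = occ$fragment[ord])
    }
  }
  best
}

# occurrences of fragments around one embedding (shared by the exported
# step operations); position_raw is the 1-based scaffold atom index
embedding_occurrences <- function(prep, tadj, mapping) {
  e <- match(as.integer(mapping) + 1L, tadj$hv)
  nheavy <- length(tadj$hv)
  inside <- logical(nheavy); inside[e] <- TRUE
  bx <- which(inside[tadj$b_a1] != inside[tadj$b_a2])
  if (length(bx) == 0) {
    return(tibble::tibble(
      position_raw = integer(0), fragment = character(0), mw = numeric(0)
    ))
  }
  outside <- which(!inside)
  okeep <- which(!inside[tadj$b_a1] & !inside[tadj$b_a2])
  gout <- igraph::graph_from_edgelist(
    cbind(match(tadj$b_a1[okeep], outside), match(tadj$b_a2[okeep], outside)),
    directed = FALSE
  )
  gout <- igraph::add_vertices(gout, max(0L, length(outside) - igraph::vcount(gout)))
  comp_of <- rep(NA_integer_, nheavy)
  comp_of[outside] <- igraph::components(gout)$membership
  occ_pos <- integer(length(bx)); occ_comp <- integer(length(bx))
  for (k in seq_along(bx)) {
    b <- bx[k]
    t_in <- if (inside[tadj$b_a1[b]]) tadj$b_a1[b] else tadj$b_a2[b]
    t_out <- if (inside[tadj$b_a1[b]]) tadj$b_a2[b] else tadj$b_a1[b]
    occ_pos[k] <- which(e == t_in)
    occ_comp[k] <- comp_of[t_out]
  }
  comp_ids <- sort(unique(occ_comp))
  frag_smi <- character(max(comp_ids)); frag_mw <- numeric(max(comp_ids))
  for (ci in comp_ids) {
    catoms <- tadj$hv[outside[comp_of[outside] == ci]]
    frag <- fragment_mol(prep, tadj, catoms, bx[occ_comp == ci], inside)
    frag_smi[ci] <- frag$smiles; frag_mw[ci] <- frag$mw
  }
  tibble::tibble(
    position_raw = occ_pos,
    fragment = frag_smi[occ_comp],
    mw = frag_mw[occ_comp]
  )
}

#' Look up a fragment in the dictionary (step V)
#'
#' Exact canonical-form lookup into the dictionary's fragment block.
#'
#' @param fragment Fragment canonical SMILES (with attachment marker).
#' @param dict An `ncmfp_dictionary`.
#' @return The 1-based fragment index, or `NA_integer_` if unknown.
#' @export
identify_fragment <- function(fragment, dict) {
  stopifnot(inherits(dict, "ncmfp_dictionary"))
  idx <- match(fragment, dict$fragments$smiles)
  if (length(idx) == 0) NA_integer_ else dict$fragments$index[idx]
}

## ---- feature dictionary ----------------------------------------------------

dict_scaffold_mols <- function(dict) {
  sc <- if (inherits(dict, "ncmfp_dictionary")) {
    dict$scaffolds[, c("smiles")]
  } else if (inherits(dict, "scaffold_library")) {
    dict$scaffolds[, c("smiles")]
  } else {
    ncmfp_abort("Need an ncmfp_dictionary or scaffold_library.", "ncmfp_input_error")
  }
  sc$mol <- lapply(sc$smiles, scaffold_mol)
  sc
}

#' Build a feature dictionary from a scaffold library and reference compounds
#'
#' Fixes the fingerprint bit layout: the scaffold block is the library in
#' (class, level, index) order; the SFCP and fragment blocks collect every
#' scaffold-fragment connection point and every distinct fragment observed
#' when decomposing the reference compounds against the library. Fragment
#' indices are assigned by ascending molecular weight (ties broken by
#' canonical form). The dictionary is deterministic given (library, reference).
#'
#' @param lib A `scaffold_library`.
#' @param reference A compound table (`mol` or `smiles` column); all compounds
#'   must contain a ring. May be empty, giving a scaffold-only dictionary.
#' @return An `ncmfp_dictionary` with blocks `scaffolds`, `sfcp`, `fragments`,
#'   total length `n_bits`, and a layout `checksum`.
#' @export
build_feature_dictionary <- function(lib, reference = NULL) {
  stopifnot(inherits(lib, "scaffold_library"))
  if (nrow(lib$scaffolds) == 0) {
    ncmfp_abort("Scaffold library is empty.", "ncmfp_input_error")
  }
  scaff <- lib$scaffolds[, c("class", "level", "index", "smiles")]
  scmols <- dict_scaffold_mols(lib)

  sfcp <- tibble::tibble(scaffold = character(0), position = integer(0))
  frags <- tibble::tibble(smiles = character(0), mw = numeric(0))
  if (!is.null(reference) && nrow(reference) > 0) {
    mols <- compound_mols(tibble::as_tibble(reference))
    for (m in mols) {
      prep <- preprocess(m)
      if (ring_count(prep) < 1) {
        ncmfp_abort("Reference compounds must contain a ring.", "ncmfp_ring_error")
      }
      dec <- ncmfp_decompose(prep, scmols)
      att <- dec$attachments
      att <- att[!is.na(att$fragment), , drop = FALSE]
      if (nrow(att) == 0) next
      sfcp <- dplyr::bind_rows(sfcp, att[, c("scaffold", "position")])
      frags <- dplyr::bind_rows(frags, att[, c("fragment", "mw")] |>
                                  stats::setNames(c("smiles", "mw")))
    }
  }
  sfcp <- dplyr::distinct(sfcp)
  # SFCP block ordered by scaffold block order, then atom position
  sc_order <- match(sfcp$scaffold, unique(scaff$smiles))
  sfcp <- sfcp[order(sc_order, sfcp$position), , drop = FALSE]
  frags <- dplyr::distinct(frags)
  frags <- dplyr::arrange(frags, .data$mw, .data$smiles)
  frags$index <- seq_len(nrow(frags))

  n_scaff <- nrow(scaff); n_sfcp <- nrow(sfcp); n_frag <- nrow(frags)
  scaff$position_bit <- seq_len(n_scaff) - 1L
  sfcp$position_bit <- n_scaff + seq_len(n_sfcp) - 1L
  frags$position_bit <- n_scaff + n_sfcp + seq_len(n_frag) - 1L

  dict <- structure(
    list(
      scaffolds = scaff, sfcp = sfcp, fragments = frags,
      n_bits = n_scaff + n_sfcp + n_frag,
      classes = lib$classes, levels = lib$levels
    ),
    class = "ncmfp_dictionary"
  )
  dict$checksum <- rlang::hash(list(dict$scaffolds, dict$sfcp, dict$fragments))
  dict
}

#' @export
print.ncmfp_dictionary <- function(x, ...) {
  cat(sprintf(
    "<ncmfp_dictionary> %d bits = %d scaffold + %d SFCP + %d fragment (checksum %s)\n",
    x$n_bits, nrow(x$scaffolds), nrow(x$sfcp), nrow(x$fragments),
    substr(x$checksum, 1, 8)
  ))
  invisible(x)
}

#' Write / read a feature dictionary as JSON
#' @param dict An `ncmfp_dictionary`.
#' @param path File path.
#' @export
write_feature_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "ncmfp_dictionary"))
  jsonlite::write_json(
    list(
      format = "ncmfp_dictionary", version = 1L,
      layout = "scaffold_block | sfcp_block | fragment_block; atom positions 0-based",
      n_bits = dict$n_bits, checksum = dict$checksum,
      classes = dict$classes, levels = dict$levels,
      scaffolds = dict$scaffolds, sfcp = dict$sfcp, fragments = dict$fragments
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_feature_dictionary
#' @export
read_feature_dictionary <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "ncmfp_dictionary")) {
    ncmfp_abort("Not a feature dictionary file.", "ncmfp_io_error")
  }
  structure(
    list(
      scaffolds = tibble::as_tibble(j$scaffolds),
      sfcp = tibble::as_tibble(j$sfcp),
      fragments = tibble::as_tibble(j$fragments),
      n_bits = as.integer(j$n_bits),
      classes = j$classes, levels = as.integer(j$levels),
      checksum = j$checksum
    ),
    class = "ncmfp_dictionary"
  )
}

## ---- fingerprint computation (step VI) --------------------------------------

#' Compute the fingerprint of a query compound
#'
#' Runs the six-step generation: the query is preprocessed, every dictionary
#' scaffold is substructure-matched, fragments and SFCPs are derived from each
#' match, fragments are identified by canonical form, and one bit is set per
#' matched scaffold, identified SFCP, and identified fragment. Unknown
#' fragments or connection points are dropped with a counter so the bit-string
#' length never changes. With `mode = "single"` only the largest matched
#' scaffold (most rings, then most atoms) contributes features.
#'
#' @param q An `ncmfp_mol` (prepared or not) with at least one ring.
#' @param dict An `ncmfp_dictionary`.
#' @param mode `"multi"` (default: all matched scaffolds) or `"single"`.
#' @return An `ncmfp_fingerprint`: bit vector plus per-bit provenance and
#'   flags `no_scaffold_match`, `unknown_fragments`, `unknown_sfcps`.
#' @export
compute_ncmfp <- function(q, dict, mode = c("multi", "single")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dict, "ncmfp_dictionary"))
  prep <- preprocess(q)
  if (ring_count(prep) < 1) {
    ncmfp_abort(
      "Fingerprints are defined only for compounds with at least one ring.",
      "ncmfp_ring_error"
    )
  }
  scmols <- dict_scaffold_mols(dict)
  dec <- ncmfp_decompose(prep, scmols)
  matched <- dec$matched
  att <- dec$attachments

  if (mode == "single" && length(matched) > 1) {
    info <- tibble::tibble(
      smiles = matched,
      rings = vapply(matched, function(s) ring_count(scaffold_mol(s)), integer(1)),
      atoms = vapply(matched, function(s) n_atoms(scaffold_mol(s)), integer(1))
    )
    info <- dplyr::arrange(info, dplyr::desc(.data$rings), dplyr::desc(.data$atoms),
                           .data$smiles)
    matched <- info$smiles[1]
    att <- att[att$scaffold == matched, , drop = FALSE]
  }

  bits <- logical(dict$n_bits)
  prov <- list()
  unknown_frags <- 0L
  unknown_sfcps <- 0L
  if (length(matched) > 0) {
    hit <- dict$scaffolds$smiles %in% matched
    bits[dict$scaffolds$position_bit[hit] + 1L] <- TRUE
    prov[[1]] <- tibble::tibble(
      bit = dict$scaffolds$position_bit[hit],
      kind = "scaffold", feature = dict$scaffolds$smiles[hit]
    )
    # SFCP features
    sf <- dplyr::distinct(att[, c("scaffold", "position")])
    if (nrow(sf) > 0) {
      key_d <- paste(dict$sfcp$scaffold, dict$sfcp$position)
      key_q <- paste(sf$scaffold, sf$position)
      hit_s <- match(key_q, key_d)
      unknown_sfcps <- sum(is.na(hit_s))
      hit_s <- hit_s[!is.na(hit_s)]
      bits[dict$sfcp$position_bit[hit_s] + 1L] <- TRUE
      prov[[2]] <- tibble::tibble(
        bit = dict$sfcp$position_bit[hit_s], kind = "sfcp",
        feature = paste0(dict$sfcp$scaffold[hit_s], "@", dict$sfcp$position[hit_s])
      )
    }
    # fragment features
    fr <- unique(att$fragment)
    unknown_frags <- sum(is.na(fr))
    fr <- fr[!is.na(fr)]
    if (length(fr) > 0) {
      hit_f <- match(fr, dict$fragments$smiles)
      unknown_frags <- unknown_frags + sum(is.na(hit_f))
      hit_f <- hit_f[!is.na(hit_f)]
      bits[dict$fragments$position_bit[hit_f] + 1L] <- TRUE
      prov[[3]] <- tibble::tibble(
        bit = dict$fragments$position_bit[hit_f], kind = "fragment",
        feature = dict$fragments$smiles[hit_f]
      )
    }
  }
  provenance <- if (length(prov) > 0) {
    dplyr::arrange(dplyr::bind_rows(prov), .data$bit)
  } else {
    tibble::tibble(bit = integer(0), kind = character(0), feature = character(0))
  }
  structure(
    list(
      bits = bits,
      set_positions = which(bits) - 1L,
      provenance = provenance,
      flags = list(
        no_scaffold_match = length(matched) == 0,
        unknown_fragments = unknown_frags,
        unknown_sfcps = unknown_sfcps
      ),
      dict_checksum = dict$checksum,
      id = if (nzchar(prep$name)) prep$name else NA_character_
    ),
    class = "ncmfp_fingerprint"
  )
}

#' @export
print.ncmfp_fingerprint <- function(x, ...) {
  cat(sprintf(
    "<ncmfp_fingerprint> %d/%d bits set%s\n",
    sum(x$bits), length(x$bits),
    if (x$flags$no_scaffold_match) " (no scaffold match)" else ""
  ))
  invisible(x)
}

#' @export
as.character.ncmfp_fingerprint <- function(x, ...) {
  paste(as.integer(x$bits), collapse = "")
}

#' Tidy fingerprint provenance
#' @param x An `ncmfp_fingerprint`.
#' @param ... Unused.
#' @return Tibble with one row per set bit: `bit` (0-based), `kind`, `feature`.
#' @method tidy ncmfp_fingerprint
#' @export
tidy.ncmfp_fingerprint <- function(x, ...) x$provenance

#' Fingerprint a compound table
#'
#' @param compounds A data frame with `id` and `mol` (or `smiles`) columns.
#' @param dict An `ncmfp_dictionary`.
#' @param mode Passed to [compute_ncmfp()].
#' @return The input tibble (minus `mol`) with columns `bits` (bit string),
#'   `n_set`, `no_scaffold_match`, `unknown_fragments`.
#' @export
ncmfp_fingerprints <- function(compounds, dict, mode = "multi") {
  compounds <- tibble::as_tibble(compounds)
  mols <- compound_mols(compounds)
  fps <- lapply(mols, compute_ncmfp, dict = dict, mode = mode)
  out <- compounds[, setdiff(names(compounds), c("mol", "input")), drop = FALSE]
  out$bits <- vapply(fps, as.character, character(1))
  out$n_set <- vapply(fps, function(f) sum(f$bits), integer(1))
  out$no_scaffold_match <- vapply(fps, function(f) f$flags$no_scaffold_match, logical(1))
  out$unknown_fragments <- vapply(fps, function(f) f$flags$unknown_fragments, integer(1))
  out
}

#' Bit-string helpers
#'
#' `fp_bits()` coerces a fingerprint, a 0/1 string, or a logical/integer
#' vector to an integer 0/1 vector; `fp_matrix()` stacks the `bits` column of
#' a fingerprint table into a 0/1 matrix (rows named by `id`).
#'
#' @param x Fingerprint-like object.
#' @export
fp_bits <- function(x) {
  if (inherits(x, "ncmfp_fingerprint")) return(as.integer(x$bits))
  if (is.character(x) && length(x) == 1) {
    return(as.integer(strsplit(x, "")[[1]]))
  }
  as.integer(x)
}

#' @rdname fp_bits
#' @param tbl A tibble with columns `id` and `bits` (as from
#'   [ncmfp_fingerprints()]).
#' @export
fp_matrix <- function(tbl) {
  m <- do.call(rbind, lapply(tbl$bits, fp_bits))
  rownames(m) <- tbl$id
  m
}

#' @rdname fp_bits
#' @details `fp_hex()` packs the bits into a hexadecimal string (4 bits per
#'   character, zero-padded at the end), a compact on-disk variant of the
#'   0/1 string.
#' @export
fp_hex <- function(x) {
  b <- fp_bits(x)
  pad <- (4 - length(b) %% 4) %% 4
  b <- c(b, rep(0L, pad))
  nib <- matrix(b, nrow = 4)
  paste(sprintf("%x", as.integer(8 * nib[1, ] + 4 * nib[2, ] +
                                   2 * nib[3, ] + nib[4, ])), collapse = "")
}
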