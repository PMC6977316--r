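#' Bemis-Murcko scaffolds and hierarchical scaffold libraries
#'
#' A molecular scaffold is obtained by removing functional groups while
#' keeping all rings, the linkers between rings, and atoms attached to a
#' retained atom by a double bond (exocyclic and terminal double bonds are
#' part of the scaffold). Ring systems are then pruned one peripheral ring at
#' a time until a single ring remains; a scaffold with r rings sits at level
#' r - 1 of the hierarchy, so level 0 scaffolds are single rings.
#'
#' @name scaffolds
NULL

## ---- smallest set of smallest rings ----------------------------------------

# Horton-style minimum cycle basis over the heavy-atom graph.
# Returns a list of atom-index vectors (1-based, original molecule indices).
sssr <- function(m) {
  hv <- heavy_idx(m)
  bkeep <- which(m$bonds$a1 %in% hv & m$bonds$a2 %in% hv)
  ne <- length(bkeep)
  el <- cbind(match(m$bonds$a1[bkeep], hv), match(m$bonds$a2[bkeep], hv))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(hv) - igraph::vcount(g)))
  mu <- ne - length(hv) + igraph::components(g)$no
  if (mu <= 0) return(list())

  ekey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  eid <- stats::setNames(seq_len(ne), ekey)
  # candidate cycles: for each vertex v and edge (x,y), SP(v,x)+SP(v,y)+(x,y)
  cand <- list()
  seen <- character(0)
  dmat <- igraph::distances(g)
  for (v in seq_along(hv)) {
    bf <- igraph::bfs(g, root = v, father = TRUE, unreachable = FALSE)
    fa <- as.integer(bf$father)
    path_to <- function(x) { # x back to v along the BFS tree
      p <- x
      while (x != v) {
        x <- fa[x]
        if (is.na(x)) return(NULL)
        p <- c(p, x)
      }
      p
    }
    for (e in seq_len(ne)) {
      x <- el[e, 1]; y <- el[e, 2]
      if (is.infinite(dmat[v, x]) || is.infinite(dmat[v, y])) next
      px <- path_to(x); py <- path_to(y)
      if (is.null(px) || is.null(py)) next
      if (length(intersect(px, py)) != 1) next # paths must share only v
      verts <- c(rev(px), py[-length(py)])     # cyclic vertex sequence
      if (length(verts) < 3 || anyDuplicated(verts)) next
      nxt <- c(verts[-1], verts[1])
      ring_edges <- eid[paste(pmin(verts, nxt), pmax(verts, nxt))]
      if (anyNA(ring_edges)) next
      ring_edges <- sort(unique(as.integer(ring_edges)))
      if (length(ring_edges) != length(verts)) next
      key <- paste(ring_edges, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- list(edges = ring_edges, verts = verts)
    }
  }
  if (length(cand) == 0) return(list())
  cand <- cand[order(lengths(lapply(cand, `[[`, "edges")))]
  # greedy GF(2) independence over edge incidence vectors
  basis <- matrix(FALSE, nrow = 0, ncol = ne)
  pivots <- integer(0)
  rings <- list()
  for (cy in cand) {
    vec <- rep(FALSE, ne); vec[cy$edges] <- TRUE
    red <- vec
    for (r in seq_len(nrow(basis))) {
      if (red[pivots[r]]) red <- xor(red, basis[r, ])
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      pivots <- c(pivots, which(red)[1])
      rings[[length(rings) + 1L]] <- hv[cy$verts]
      if (length(rings) == mu) break
    }
  }
  rings
}

## ---- framework extraction ---------------------------------------------------

# Core Bemis-Murcko reduction: keep the 2-core of the heavy-atom graph (rings
# plus inter-ring linkers), then re-attach atoms multiple-bonded to a kept
# atom until stable. Removed substituents are replaced by hydrogens.
bm_cleanup <- function(m) {
  hv <- heavy_idx(m)
  if (length(hv) == 0) return(NULL)
  adj <- vector("list", n_atoms(m))
  for (i in seq_len(nrow(m$bonds))) {
    a1 <- m$bonds$a1[i]; a2 <- m$bonds$a2[i]
    if (m$atoms$element[a1] == "H" || m$atoms$element[a2] == "H") next
    adj[[a1]] <- c(adj[[a1]], a2); adj[[a2]] <- c(adj[[a2]], a1)
  }
  keep <- rep(FALSE, n_atoms(m)); keep[hv] <- TRUE
  # iteratively strip degree-<=1 atoms (2-core)
  repeat {
    deg <- vapply(seq_along(adj), function(a) {
      if (!keep[a]) return(99L)
      sum(keep[adj[[a]]])
    }, integer(1))
    drop <- which(keep & deg <= 1L)
    if (length(drop) == 0) break
    keep[drop] <- FALSE
  }
  if (!any(keep)) return(NULL)
  # re-attach atoms connected to the core by a multiple bond (exocyclic and
  # terminal double bonds belong to the scaffold)
  repeat {
    added <- FALSE
    for (i in seq_len(nrow(m$bonds))) {
      if (m$bonds$order[i] < 2L) next
      a1 <- m$bonds$a1[i]; a2 <- m$bonds$a2[i]
      if (m$atoms$element[a1] == "H" || m$atoms$element[a2] == "H") next
      if (keep[a1] && !keep[a2]) { keep[a2] <- TRUE; added <- TRUE }
      else if (keep[a2] && !keep[a1]) { keep[a1] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }
  submol(m, which(keep))
}

#' Extract the Bemis-Murcko framework of a molecule
#'
#' Removes all side-chain atoms, retaining every ring atom, every linker atom
#' between rings, and any atom attached to a retained atom by a double (or
#' triple) bond. The framework of a framework is itself (idempotent).
#'
#' @param m An `ncmfp_mol` containing at least one ring.
#' @return An `ncmfp_mol` framework.
#' @examples
#' canonical_form(murcko_framework(parse_structure("CCc1ccccc1"))) # benzene
#' @export
murcko_framework <- function(m) {
  stopifnot(inherits(m, "ncmfp_mol"))
  if (ring_count(m) < 1) {
    ncmfp_abort("Molecule contains no ring; no scaffold exists.", "ncmfp_no_scaffold_error")
  }
  fw <- bm_cleanup(m)
  if (is.null(fw) || n_atoms(fw) == 0) {
    ncmfp_abort("Framework extraction removed all atoms.", "ncmfp_no_scaffold_error")
  }
  fw$name <- m$name
  fw
}

## ---- ring pruning -----------------------------------------------------------

# parse a canonical scaffold SMILES with caching; the canonical atom order of
# this parse defines the scaffold's own 0-based SFCP positions
scaffold_mol <- function(smiles) {
  ncmfp_cache(paste0("mol::", smiles), function() parse_structure(smiles))
}

#' Remove one peripheral ring from a scaffold
#'
#' Returns every chemically valid scaffold obtainable from `s` by deleting the
#' atoms exclusive to one of its rings (smallest set of smallest rings) and
#' then re-applying the framework cleanup, deduplicated by canonical form.
#' Candidates that disconnect the scaffold, fail to lower the ring count by
#' exactly one, or cannot be re-perceived as a valid structure are discarded
#' (the latter with a logged note).
#'
#' @param s An `ncmfp_mol` scaffold.
#' @return A named list of `ncmfp_mol` (names are canonical forms); empty for
#'   single-ring scaffolds.
#' @export
prune_one_ring <- function(s) {
  stopifnot(inherits(s, "ncmfp_mol"))
  nr <- ring_count(s)
  if (nr <= 1) return(list())
  rings <- sssr(s)
  out <- list()
  for (ri in seq_along(rings)) {
    ring <- rings[[ri]]
    others <- unique(unlist(rings[-ri]))
    excl <- setdiff(ring, others)
    if (length(excl) == 0) next
    keep <- setdiff(heavy_idx(s), excl)
    if (length(keep) == 0) next
    cand <- submol(s, keep)
    cand <- bm_cleanup(cand)
    if (is.null(cand) || n_atoms(cand) == 0) next
    if (length(mol_components(cand)) != 1) next
    if (ring_count(cand) != nr - 1L) next
    cf <- canonical_form(cand)
    if (is.na(cf)) {
      rlang::inform(
        sprintf("Discarding chemically invalid pruned scaffold of '%s'.", s$name),
        class = "ncmfp_note"
      )
      next
    }
    if (!cf %in% names(out)) {
      reparsed <- tryCatch(scaffold_mol(cf), error = function(e) NULL)
      if (is.null(reparsed)) next
      out[[cf]] <- reparsed
    }
  }
  out
}

#' Enumerate the full scaffold hierarchy of a molecule
#'
#' Builds the complete pruning tree from the molecule's Bemis-Murcko framework
#' down to single rings, collecting every scaffold encountered. All one-ring
#' removals are explored (a scaffold network, not a single chain), so a level
#' may hold several scaffolds. Level = ring count - 1.
#'
#' @param m An `ncmfp_mol` with at least one ring.
#' @return A tibble with columns `level` (integer), `smiles` (canonical form)
#'   and `mol` (list of `ncmfp_mol`), one row per distinct scaffold, ordered by
#'   level then canonical form.
#' @export
enumerate_levels <- function(m) {
  fw <- murcko_framework(m)
  fw_cf <- canonical_form(fw)
  if (is.na(fw_cf)) {
    ncmfp_abort("Framework could not be canonicalized.", "ncmfp_no_scaffold_error")
  }
  root <- scaffold_mol(fw_cf)
  seen <- character(0)
  rows <- list()
  queue <- stats::setNames(list(root), fw_cf)
  while (length(queue) > 0) {
    cf <- names(queue)[1]
    s <- queue[[1]]
    queue <- queue[-1]
    if (cf %in% seen) next
    seen <- c(seen, cf)
    rows[[cf]] <- tibble::tibble(
      level = ring_count(s) - 1L, smiles = cf, mol = list(s)
    )
    if (ring_count(s) > 1) {
      kids <- ncmfp_cache(paste0("prune::", cf), function() prune_one_ring(s))
      for (kcf in names(kids)) {
        if (!kcf %in% seen && !kcf %in% names(queue)) {
          queue[[kcf]] <- kids[[kcf]]
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$level, .data$smiles)
}

## ---- scaffold libraries ------------------------------------------------------

#' Build a class-wise scaffold library
#'
#' For each compound class, the scaffold hierarchies of all its compounds are
#' pooled, restricted to the requested levels, and deduplicated by canonical
#' form within each (class, level) cell. Duplicates across classes are
#' retained. Within a cell scaffolds are ordered lexicographically by
#' canonical form, so the index k of scaffold s(i)[j,k] is reproducible.
#'
#' @param compounds A data frame with columns `class` and either `mol` (list of
#'   `ncmfp_mol`) or `smiles`; typically the output of [read_compound_set()] or
#'   [generate_dataset()].
#' @param levels Integer vector of scaffold levels to keep (default `c(1, 2)`,
#'   the levels used for fingerprint scaffold blocks).
#' @return A `scaffold_library` object; see [tidy.scaffold_library()].
#' @export
build_library <- function(compounds, levels = c(1L, 2L)) {
  compounds <- tibble::as_tibble(compounds)
  if (!"class" %in% names(compounds) || anyNA(compounds$class)) {
    offenders <- if ("id" %in% names(compounds)) {
      compounds$id[if ("class" %in% names(compounds)) is.na(compounds$class) else TRUE]
    } else which(if ("class" %in% names(compounds)) is.na(compounds$class) else TRUE)
    ncmfp_abort(
      paste0("Every compound needs a class label; offenders: ",
             paste(utils::head(offenders, 10), collapse = ", ")),
      "ncmfp_label_error"
    )
  }
  mols <- compound_mols(compounds)
  levels <- sort(unique(as.integer(levels)))
  class_order <- unique(as.character(compounds$class))

  per_comp <- purrr::map2(mols, as.character(compounds$class), function(m, cl) {
    sc <- enumerate_levels(m)
    sc <- sc[sc$level %in% levels, c("level", "smiles")]
    if (nrow(sc) == 0) return(NULL)
    sc$class <- cl
    sc
  })
  scaff <- dplyr::bind_rows(per_comp)
  if (is.null(scaff) || nrow(scaff) == 0) {
    scaff <- tibble::tibble(level = integer(0), smiles = character(0), class = character(0))
  }
  scaff <- dplyr::distinct(scaff, .data$class, .data$level, .data$smiles)
  scaff$class <- factor(scaff$class, levels = class_order)
  scaff <- dplyr::arrange(scaff, .data$class, .data$level, .data$smiles)
  scaff <- dplyr::mutate(
    dplyr::group_by(scaff, .data$class, .data$level),
    index = dplyr::row_number()
  )
  scaff <- dplyr::ungroup(scaff)
  scaff$class <- as.character(scaff$class)
  scaff$n_rings <- scaff$level + 1L
  scaff <- scaff[, c("class", "level", "index", "smiles", "n_rings")]

  structure(
    list(
      scaffolds = scaff,
      classes = class_order,
      levels = levels,
      provenance = list(
        n_compounds = nrow(compounds),
        per_class = dplyr::count(
          tibble::tibble(class = factor(compounds$class, levels = class_order)),
          .data$class, name = "n_compounds"
        )
      )
    ),
    class = "scaffold_library"
  )
}

# resolve a compound table's structures into a list of ncmfp_mol
compound_mols <- function(tbl) {
  if ("mol" %in% names(tbl)) return(tbl$mol)
  if (!"smiles" %in% names(tbl)) {
    ncmfp_abort("Compound table needs a `mol` or `smiles` column.", "ncmfp_input_error")
  }
  ids <- if ("id" %in% names(tbl)) tbl$id else as.character(seq_len(nrow(tbl)))
  purrr::map2(tbl$smiles, ids, function(s, i) parse_structure(s, id = i))
}

#' @export
print.scaffold_library <- function(x, ...) {
  cat(sprintf(
    "<scaffold_library> %d scaffold(s), %d class(es), levels %s\n",
    nrow(x$scaffolds), length(x$classes), paste(x$levels, collapse = ",")
  ))
  print(summary_counts(x))
  invisible(x)
}

summary_counts <- function(lib) {
  tidyr::pivot_wider(
    dplyr::count(lib$scaffolds, .data$class, .data$level),
    names_from = "level", values_from = "n", names_prefix = "level_",
    values_fill = 0L
  )
}

#' Tidy a scaffold library
#'
#' @param x A `scaffold_library`.
#' @param ... Unused.
#' @return A tibble with one row per scaffold: class, level, index, canonical
#'   SMILES, ring count.
#' @method tidy scaffold_library
#' @export
tidy.scaffold_library <- function(x, ...) x$scaffolds

#' One-row summary of a scaffold library
#' @param x A `scaffold_library`.
#' @param ... Unused.
#' @method glance scaffold_library
#' @export
glance.scaffold_library <- function(x, ...) {
  tibble::tibble(
    n_scaffolds = nrow(x$scaffolds),
    n_classes = length(x$classes),
    n_levels = length(x$levels),
    n_compounds = x$provenance$n_compounds
  )
}

#' Plot per-class scaffold counts by level
#' @param object A `scaffold_library`.
#' @param ... Unused.
#' @method autoplot scaffold_library
#' @export
autoplot.scaffold_library <- function(object, ...) {
  d <- dplyr::count(object$scaffolds, .data$class, .data$level)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$class, y = .data$n, fill = factor(.data$level)
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "class", y = "scaffolds", fill = "level") +
    ggplot2::theme_minimal()
}

## ---- library persistence -----------------------------------------------------

#' Write / read a scaffold library as JSON
#'
#' @param lib A `scaffold_library`.
#' @param path File path.
#' @return `read_scaffold_library()` returns a `scaffold_library`;
#'   `write_scaffold_library()` returns `path` invisibly.
#' @export
write_scaffold_library <- function(lib, path) {
  stopifnot(inherits(lib, "scaffold_library"))
  jsonlite::write_json(
    list(
      format = "ncmfp_scaffold_library",
      version = 1L,
      classes = lib$classes,
      levels = lib$levels,
      scaffolds = lib$scaffolds,
      provenance = lib$provenance
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_scaffold_library
#' @export
read_scaffold_library <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "ncmfp_scaffold_library")) {
    ncmfp_abort("Not a scaffold library file.", "ncmfp_io_error")
  }
  structure(
    list(
      scaffolds = tibble::as_tibble(j$scaffolds),
      classes = j$classes,
      levels = as.integer(j$levels),
      provenance = j$provenance
    ),
    class = "scaffold_library"
  )
}
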