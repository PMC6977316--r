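#' Substructure matching
#'
#' Exact subgraph-isomorphism matching over heavy-atom graphs. Aromatic atoms
#' and bonds match only aromatic counterparts, so an aromatic ring never
#' matches its saturated analogue (benzene does not match cyclohexane).
#' Matching ignores formal charge and stereochemistry.
#'
#' Candidate embeddings are enumerated with igraph's LAD solver (non-induced,
#' with per-atom domains restricting element and aromaticity) and then
#' filtered for bond-type compatibility.
#'
#' @name substructure-matching
NULL

mol_graph_heavy <- function(m) {
  hv <- heavy_idx(m)
  bkeep <- which(m$bonds$a1 %in% hv & m$bonds$a2 %in% hv)
  el <- cbind(match(m$bonds$a1[bkeep], hv), match(m$bonds$a2[bkeep], hv))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(hv) - igraph::vcount(g)))
  list(
    g = g, idx = hv,
    element = m$atoms$element[hv],
    aromatic = m$atoms$aromatic[hv],
    b_from = el[, 1], b_to = el[, 2],
    b_order = m$bonds$order[bkeep],
    b_arom = m$bonds$aromatic[bkeep],
    degree = igraph::degree(g)
  )
}

# all embeddings of pattern heavy graph into target heavy graph;
# returns list of integer vectors: pattern heavy-atom i -> target heavy-atom
# (indices into the heavy-atom ordering, which equals atom order for
# hydrogen-collapsed molecules)
match_heavy <- function(pg, tg) {
  np <- length(pg$element); nt <- length(tg$element)
  if (np == 0 || np > nt) return(list())
  domains <- vector("list", np)
  for (i in seq_len(np)) {
    dom <- which(
      tg$element == pg$element[i] &
        tg$aromatic == pg$aromatic[i] &
        tg$degree >= pg$degree[i]
    )
    if (length(dom) == 0) return(list())
    domains[[i]] <- dom
  }
  if (np == 1) {
    return(lapply(domains[[1]], function(j) j))
  }
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(
      pattern = pg$g, target = tg$g,
      method = "lad", induced = FALSE, domains = domains
    ),
    error = function(e) list()
  )
  if (length(maps) == 0) return(list())
  # bond-type filter: every pattern bond must land on a compatible target bond
  tkey <- paste(pmin(tg$b_from, tg$b_to), pmax(tg$b_from, tg$b_to))
  tinfo <- stats::setNames(seq_along(tkey), tkey)
  ok <- vapply(maps, function(mp) {
    mp <- as.integer(mp)
    for (b in seq_along(pg$b_from)) {
      u <- mp[pg$b_from[b]]; v <- mp[pg$b_to[b]]
      ti <- tinfo[[paste(min(u, v), max(u, v))]]
      if (is.null(ti)) return(FALSE)
      if (pg$b_arom[b] != tg$b_arom[ti]) return(FALSE)
      if (!pg$b_arom[b] && pg$b_order[b] != tg$b_order[ti]) return(FALSE)
    }
    TRUE
  }, logical(1))
  lapply(maps[ok], as.integer)
}

#' Find all embeddings of a pattern in a target molecule
#'
#' Enumerates every subgraph-isomorphism embedding of `pattern` into `target`.
#' An empty list means no match. Symmetric patterns return one embedding per
#' automorphic image (benzene into benzene gives 12).
#'
#' @param pattern An `ncmfp_mol` with at least one atom.
#' @param target An `ncmfp_mol` (typically a prepared molecule).
#' @return A list of atom mappings; each mapping is a tibble with columns
#'   `pattern_atom` and `target_atom` (0-based atom indices).
#' @examples
#' benzene <- parse_structure("c1ccccc1")
#' toluene <- preprocess(parse_structure("Cc1ccccc1"))
#' length(match_substructure(benzene, toluene)) # 12
#' @export
match_substructure <- function(pattern, target) {
  stopifnot(inherits(pattern, "ncmfp_mol"), inherits(target, "ncmfp_mol"))
  if (n_atoms(pattern) < 1) {
    ncmfp_abort("Pattern must contain at least one atom.", "ncmfp_match_error")
  }
  pg <- mol_graph_heavy(pattern); tg <- mol_graph_heavy(target)
  maps <- match_heavy(pg, tg)
  lapply(maps, function(mp) {
    structure(
      tibble::tibble(
        pattern_atom = pg$idx[seq_along(mp)] - 1L,
        target_atom = tg$idx[mp] - 1L
      ),
      class = c("ncmfp_atom_mapping", "tbl_df", "tbl", "data.frame"),
      pattern = pattern, target = target
    )
  })
}

# automorphism group of a molecule's heavy graph (list of permutations,
# 1-based over heavy atoms); cached by canonical form when available
mol_automorphisms <- function(m, key = NULL) {
  compute <- function() {
    g <- mol_graph_heavy(m)
    match_heavy(g, g)
  }
  if (is.null(key)) compute() else ncmfp_cache(paste0("aut::", key), compute)
}
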