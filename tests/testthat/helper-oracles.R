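# Independent oracles and fixture utilities used across the test files.

# ---- fixtures ----------------------------------------------------------------

fixture_smiles <- c(
  benzene        = "c1ccccc1",
  toluene        = "Cc1ccccc1",
  phenol         = "Oc1ccccc1",
  pyridine       = "c1ccncc1",
  cyclohexane    = "C1CCCCC1",
  cyclohexanone  = "O=C1CCCCC1",
  naphthalene    = "c1ccc2ccccc2c1",
  biphenyl       = "c1ccccc1-c1ccccc1",
  diphenylmethane = "c1ccccc1Cc1ccccc1",
  p_terphenyl    = "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1",
  indole         = "c1ccc2[nH]ccc2c1",
  quinoline      = "c1ccc2ncccc2c1",
  anthracene     = "c1ccc2cc3ccccc3cc2c1",
  spiro_decane   = "C1CCC2(CC1)CCCC2",
  norbornane     = "C1CC2CCC1C2",
  coumarin       = "O=c1ccc2ccccc2o1",
  decorated_naphthalene = "Cc1ccc2ccccc2c1O",
  phenyl_cyclohexane = "C1CCCCC1c1ccccc1"
)

fixture_mol <- function(name) parse_structure(fixture_smiles[[name]], id = name)

# toy 4-bit dictionary: benzene scaffold, references toluene + phenol
toy_dictionary <- function() {
  comps <- tibble::tibble(
    id = c("toluene", "phenol"),
    smiles = c("Cc1ccccc1", "Oc1ccccc1"),
    class = "toy"
  )
  lib <- build_library(comps, levels = 0)
  build_feature_dictionary(lib, comps)
}

# ---- atom permutation --------------------------------------------------------

# reorder a molecule's atoms by a random permutation; bonds remapped
permute_mol <- function(m, perm = sample(nrow(m$atoms))) {
  inv <- order(perm)
  at <- m$atoms[perm, , drop = FALSE]
  bd <- m$bonds
  bd$a1 <- inv[bd$a1]
  bd$a2 <- inv[bd$a2]
  out <- ncmfp:::new_mol(at, bd, name = m$name)
  class(out) <- class(m)
  out
}

# reparse a molecule through a reordered SMILES rendering (exercises both the
# writer and Open Babel's reader under atom relabelling)
reparse_permuted <- function(m) {
  pm <- permute_mol(m)
  parse_structure(ncmfp:::write_smiles(pm))
}

# ---- brute-force subgraph isomorphism ----------------------------------------

# exhaustive backtracking matcher, independent of igraph's LAD solver;
# returns the set of pattern->target assignments (heavy atoms, 1-based)
bf_match <- function(pattern, target) {
  ph <- ncmfp:::heavy_idx(pattern)
  th <- ncmfp:::heavy_idx(target)
  pa <- pattern$atoms[ph, , drop = FALSE]
  ta <- target$atoms[th, , drop = FALSE]
  pb <- pattern$bonds[pattern$bonds$a1 %in% ph & pattern$bonds$a2 %in% ph, , drop = FALSE]
  tb <- target$bonds[target$bonds$a1 %in% th & target$bonds$a2 %in% th, , drop = FALSE]
  pb$a1 <- match(pb$a1, ph); pb$a2 <- match(pb$a2, ph)
  tb$a1 <- match(tb$a1, th); tb$a2 <- match(tb$a2, th)
  np <- nrow(pa); nt <- nrow(ta)
  if (np == 0 || np > nt) return(list())
  tkey <- paste(pmin(tb$a1, tb$a2), pmax(tb$a1, tb$a2))
  tbond <- stats::setNames(seq_len(nrow(tb)), tkey)
  padj <- lapply(seq_len(np), function(i) {
    c(pb$a2[pb$a1 == i], pb$a1[pb$a2 == i])
  })
  results <- list()
  assign_next <- function(i, map, used) {
    if (i > np) {
      results[[length(results) + 1L]] <<- map
      return(invisible())
    }
    for (j in seq_len(nt)) {
      if (used[j]) next
      if (ta$element[j] != pa$element[i] || ta$aromatic[j] != pa$aromatic[i]) next
      ok <- TRUE
      for (k in padj[[i]]) {
        if (k >= i) next # neighbour not assigned yet
        u <- map[k]
        bkey <- paste(min(u, j), max(u, j))
        ti <- unname(tbond[bkey])
        if (is.na(ti)) { ok <- FALSE; break }
        pi <- which((pb$a1 == i & pb$a2 == k) | (pb$a1 == k & pb$a2 == i))[1]
        if (pb$aromatic[pi] != tb$aromatic[ti]) { ok <- FALSE; break }
        if (!pb$aromatic[pi] && pb$order[pi] != tb$order[ti]) { ok <- FALSE; break }
      }
      if (!ok) next
      map[i] <- j; used[j] <- TRUE
      assign_next(i + 1L, map, used)
      used[j] <- FALSE
    }
  }
  assign_next(1L, integer(np), logical(nt))
  results
}

# ---- brute-force scaffold hierarchy ------------------------------------------

# Ring-subset enumerator: instead of iterative one-ring pruning, enumerate all
# subsets of the framework's SSSR rings, reconstruct the candidate scaffold
# (ring atoms + connecting shortest paths + multiple-bond partners), and keep
# those that are connected with exactly |subset| rings.
bf_enumerate_levels <- function(m) {
  fw <- murcko_framework(m)
  rings <- ncmfp:::sssr(fw)
  nr <- length(rings)
  hv <- ncmfp:::heavy_idx(fw)
  bk <- fw$bonds[fw$bonds$a1 %in% hv & fw$bonds$a2 %in% hv, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    cbind(match(bk$a1, hv), match(bk$a2, hv)), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(hv) - igraph::vcount(g)))
  out <- list()
  for (mask in seq_len(2^nr - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nr) - 1L)) > 0)
    atoms <- unique(unlist(rings[sel]))
    # connect every pair of selected rings along shortest paths that do not
    # run through atoms exclusive to unselected rings (those atoms are gone
    # after pruning, so such a subset is unreachable)
    feasible <- TRUE
    if (length(sel) > 1) {
      forbidden <- setdiff(unique(unlist(rings[-sel])), atoms)
      gsub <- igraph::delete_vertices(g, match(forbidden, hv))
      kept <- setdiff(seq_along(hv), match(forbidden, hv))
      for (i in seq_along(sel)) {
        for (j in seq_along(sel)) {
          if (j <= i || !feasible) next
          a_set <- match(match(rings[[sel[i]]], hv), kept)
          b_set <- match(match(rings[[sel[j]]], hv), kept)
          best <- NULL; best_len <- Inf
          for (a in a_set) {
            sp <- suppressWarnings(
              igraph::shortest_paths(gsub, from = a, to = b_set)$vpath
            )
            for (p in sp) {
              if (length(p) > 0 && length(p) < best_len) {
                best <- as.integer(p); best_len <- length(p)
              }
            }
          }
          if (is.null(best)) feasible <- FALSE
          else atoms <- unique(c(atoms, hv[kept[best]]))
        }
      }
    }
    if (!feasible) next
    # multiple-bond partners belong to the scaffold
    repeat {
      extra <- fw$bonds$a2[fw$bonds$order >= 2 & fw$bonds$a1 %in% atoms &
                             !fw$bonds$a2 %in% atoms]
      extra <- c(extra, fw$bonds$a1[fw$bonds$order >= 2 & fw$bonds$a2 %in% atoms &
                                      !fw$bonds$a1 %in% atoms])
      extra <- intersect(unique(extra), hv)
      if (length(extra) == 0) break
      atoms <- c(atoms, extra)
    }
    cand <- ncmfp:::submol(fw, atoms)
    if (length(ncmfp:::mol_components(cand)) != 1) next
    if (ring_count(cand) != length(sel)) next
    cf <- canonical_form(cand)
    if (is.na(cf)) next
    lv <- length(sel) - 1L
    out[[cf]] <- tibble::tibble(level = lv, smiles = cf)
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(dplyr::distinct(res), level, smiles)
}

# ---- independent metric recomputation ----------------------------------------

# textbook formulas written independently of confusion_metrics()
bf_metrics <- function(tp, fp, tn, fn) {
  tot <- tp + fp + tn + fn
  div <- function(a, b) if (b == 0) 0 else a / b
  prec <- div(tp, tp + fp)
  sens <- div(tp, tp + fn)
  mccd <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    accuracy = (tp + tn) / tot,
    sensitivity = sens,
    specificity = div(tn, tn + fp),
    precision = prec,
    f1 = div(2 * prec * sens, prec + sens),
    mcc = if (mccd == 0) 0 else (tp * tn - fp * fn) / mccd
  )
}
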