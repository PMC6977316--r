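#' Attributed molecular graphs
#'
#' Molecules are stored as small graph objects: a tibble of heavy atoms
#' (element, formal charge, aromatic flag, implicit hydrogen count) and a
#' tibble of bonds (atom index pair, bond order, aromatic flag). Atom indices
#' are contiguous and 1-based internally; every user-facing position (for
#' example scaffold-fragment connection points) is reported 0-based, matching
#' the atomic indices assigned during preprocessing.
#'
#' Parsing, hydrogen addition, aromaticity perception and canonicalization are
#' delegated to Open Babel through \pkg{ChemmineOB}; the package itself only
#' edits the resulting graphs (scaffold pruning, fragment cutting).
#'
#' @name ncmfp_mol
NULL

new_mol <- function(atoms, bonds, name = "") {
  structure(list(atoms = atoms, bonds = bonds, name = name), class = "ncmfp_mol")
}

#' @export
print.ncmfp_mol <- function(x, ...) {
  cat(sprintf(
    "<ncmfp_mol%s> %d heavy atoms, %d bonds, %d ring(s)\n",
    if (inherits(x, "ncmfp_prepared")) " (prepared)" else "",
    sum(x$atoms$element != "H"), nrow(x$bonds), ring_count(x)
  ))
  if (nzchar(x$name)) cat("name:", x$name, "\n")
  invisible(x)
}

n_atoms <- function(m) nrow(m$atoms)
heavy_idx <- function(m) which(m$atoms$element != "H")

#' Number of rings of a molecule
#'
#' The ring count is the cyclomatic number (bonds - atoms + components) of the
#' heavy-atom graph, which equals the size of the smallest set of smallest
#' rings. Scaffold levels are defined as `ring_count - 1`.
#'
#' @param m An `ncmfp_mol`.
#' @return Integer ring count.
#' @export
ring_count <- function(m) {
  stopifnot(inherits(m, "ncmfp_mol"))
  hv <- heavy_idx(m)
  if (length(hv) == 0) return(0L)
  keep <- m$bonds$a1 %in% hv & m$bonds$a2 %in% hv
  g <- igraph::graph_from_edgelist(
    cbind(match(m$bonds$a1[keep], hv), match(m$bonds$a2[keep], hv)),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(hv) - igraph::vcount(g)))
  as.integer(sum(keep) - length(hv) + igraph::components(g)$no)
}

## ---- Open Babel bridge -----------------------------------------------------

ob_convert <- function(from, to, text, add_h = FALSE) {
  opts <- if (add_h) {
    data.frame(names = "h", args = "")
  } else {
    data.frame(names = character(0), args = character(0))
  }
  tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = text, options = opts)),
    error = function(e) ""
  )
}

parse_mol2_block <- function(block, name = "") {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  sec <- cumsum(grepl("^@<TRIPOS>", lines))
  headers <- grep("^@<TRIPOS>", lines, value = TRUE)
  get_section <- function(what) {
    i <- which(headers == paste0("@<TRIPOS>", what))
    if (length(i) == 0) return(character(0))
    body <- lines[sec == i[1]][-1]
    body[nzchar(trimws(body))]
  }
  atom_lines <- get_section("ATOM")
  if (length(atom_lines) == 0) return(NULL)
  af <- do.call(rbind, strsplit(trimws(atom_lines), "\\s+"))
  type <- af[, 6]
  element <- sub("\\..*$", "", type)
  element[element == "Du"] <- "*"
  # Normalise case: OB atom types are already element-cased (Cl, Br, ...)
  aromatic_atom <- grepl("\\.ar$", type)

  bond_lines <- get_section("BOND")
  if (length(bond_lines) > 0) {
    bf <- do.call(rbind, strsplit(trimws(bond_lines), "\\s+"))
    btype <- bf[, 4]
    order <- ifelse(btype == "ar", 1L, ifelse(btype == "am", 1L,
      suppressWarnings(as.integer(btype))
    ))
    order[is.na(order)] <- 1L
    bonds <- tibble::tibble(
      a1 = as.integer(bf[, 2]), a2 = as.integer(bf[, 3]),
      order = order, aromatic = btype == "ar"
    )
  } else {
    bonds <- tibble::tibble(
      a1 = integer(0), a2 = integer(0), order = integer(0), aromatic = logical(0)
    )
  }
  # atoms on aromatic bonds are aromatic even when typed e.g. O.2 (pyranones)
  aromatic_atom[unique(c(bonds$a1[bonds$aromatic], bonds$a2[bonds$aromatic]))] <- TRUE

  charge <- integer(nrow(af))
  attr_lines <- get_section("UNITY_ATOM_ATTR")
  i <- 1L
  while (i < length(attr_lines)) {
    head <- strsplit(trimws(attr_lines[i]), "\\s+")[[1]]
    aid <- as.integer(head[1]); nattr <- as.integer(head[2])
    for (k in seq_len(nattr)) {
      kv <- strsplit(trimws(attr_lines[i + k]), "\\s+")[[1]]
      if (kv[1] == "charge") charge[aid] <- as.integer(kv[2])
    }
    i <- i + 1L + nattr
  }

  atoms <- tibble::tibble(
    element = element, charge = charge,
    aromatic = aromatic_atom, hcount = 0L
  )
  collapse_hydrogens(new_mol(atoms, bonds, name = name))
}

# Fold explicit hydrogen atoms into per-heavy-atom hcount fields.
collapse_hydrogens <- function(m) {
  is_h <- m$atoms$element == "H"
  if (!any(is_h)) return(m)
  keep <- which(!is_h)
  remap <- match(seq_len(nrow(m$atoms)), keep)
  hc <- m$atoms$hcount[keep]
  for (i in seq_len(nrow(m$bonds))) {
    a1 <- m$bonds$a1[i]; a2 <- m$bonds$a2[i]
    if (is_h[a1] && !is_h[a2]) hc[remap[a2]] <- hc[remap[a2]] + 1L
    if (is_h[a2] && !is_h[a1]) hc[remap[a1]] <- hc[remap[a1]] + 1L
  }
  bkeep <- !is_h[m$bonds$a1] & !is_h[m$bonds$a2]
  bonds <- m$bonds[bkeep, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  atoms <- m$atoms[keep, , drop = FALSE]
  atoms$hcount <- hc
  new_mol(atoms, bonds, name = m$name)
}

#' Parse a compound structure
#'
#' Reads a single SMILES string or an SDF (V2000) record into a molecular
#' graph. Aromaticity is perceived at parse time (Open Babel model) and
#' hydrogens are folded into per-atom counts; [preprocess()] materialises
#' them as explicit atoms.
#'
#' @param text SMILES string (optionally followed by whitespace and a name) or
#'   the text of one SDF record.
#' @param format `"smiles"` or `"sdf"`.
#' @param id Optional record identifier used in error messages.
#' @return An `ncmfp_mol`.
#' @examples
#' parse_structure("c1ccccc1", id = "benzene")
#' @export
parse_structure <- function(text, format = c("smiles", "sdf"), id = NULL) {
  format <- match.arg(format)
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    ncmfp_abort("`text` must be a non-empty string.", "ncmfp_parse_error", id = id)
  }
  if (format == "smiles") {
    parts <- strsplit(trimws(text), "\\s+")[[1]]
    smi <- parts[1]
    name <- if (is.null(id)) paste(parts[-1], collapse = " ") else id
    mol2 <- ob_convert("SMI", "MOL2", paste0(smi, "\n"), add_h = TRUE)
  } else {
    name <- if (is.null(id)) trimws(strsplit(text, "\n")[[1]][1]) else id
    rec <- text
    if (!grepl("\\$\\$\\$\\$", rec)) rec <- paste0(rec, "\n$$$$\n")
    mol2 <- ob_convert("SDF", "MOL2", rec, add_h = TRUE)
  }
  if (!nzchar(mol2) || !grepl("@<TRIPOS>ATOM", mol2)) {
    ncmfp_abort(
      sprintf("Failed to parse %s record%s.", format,
              if (is.null(id)) "" else paste0(" '", id, "'")),
      "ncmfp_parse_error", id = id
    )
  }
  m <- parse_mol2_block(mol2, name = if (is.na(name)) "" else name)
  if (is.null(m) || n_atoms(m) == 0) {
    ncmfp_abort("Parsed molecule has no atoms.", "ncmfp_parse_error", id = id)
  }
  m
}

## ---- SMILES writer ---------------------------------------------------------

# Deterministic SMILES writer used to hand edited graphs back to Open Babel
# for canonicalization. Every atom is written in brackets with its explicit
# hydrogen count, so no valence model is needed on the way out.
atom_token <- function(el, charge, aromatic, hcount) {
  if (el == "*") return("*")
  sym <- if (aromatic && el %in% AROMATIC_ELEMENTS) {
    paste0(tolower(substr(el, 1, 1)), substr(el, 2, nchar(el)))
  } else {
    el
  }
  h <- if (hcount == 1) "H" else if (hcount > 1) paste0("H", hcount) else ""
  ch <- if (charge == 1) "+" else if (charge == -1) "-" else if (charge > 1) {
    paste0("+", charge)
  } else if (charge < -1) as.character(charge) else ""
  paste0("[", sym, h, ch, "]")
}

bond_token <- function(order, aromatic, a1_ar, a2_ar) {
  if (aromatic) return("")
  if (order == 2L) return("=")
  if (order == 3L) return("#")
  if (a1_ar && a2_ar) return("-") # single bond between aromatic atoms
  ""
}

#' @noRd
write_smiles <- function(m, order = NULL) {
  hv <- heavy_idx(m)
  if (length(hv) == 0) return("")
  at <- m$atoms
  # adjacency over heavy atoms with bond attributes
  nb <- vector("list", nrow(at))
  bheavy <- which(m$bonds$a1 %in% hv & m$bonds$a2 %in% hv)
  for (bi in bheavy) {
    a1 <- m$bonds$a1[bi]; a2 <- m$bonds$a2[bi]
    nb[[a1]] <- c(nb[[a1]], stats::setNames(bi, a2))
    nb[[a2]] <- c(nb[[a2]], stats::setNames(bi, a1))
  }
  visit_order <- if (is.null(order)) hv else order

  # pass 1: DFS to classify bonds into spanning-tree edges and ring closures
  visited <- logical(nrow(at))
  used_bond <- logical(nrow(m$bonds))
  back_edges <- integer(0)
  dfs_back <- function(a) {
    visited[a] <<- TRUE
    nbs <- nb[[a]]
    if (length(nbs) > 0) nbs <- nbs[order(as.integer(names(nbs)))]
    for (k in seq_along(nbs)) {
      bi <- nbs[k]; b <- as.integer(names(nbs)[k])
      if (used_bond[bi]) next
      used_bond[bi] <<- TRUE
      if (visited[b]) back_edges <<- c(back_edges, bi) else dfs_back(b)
    }
  }
  roots <- integer(0)
  for (a in visit_order) {
    if (!visited[a] && at$element[a] != "H") { roots <- c(roots, a); dfs_back(a) }
  }
  # pass 2: emit, with ring-closure digits attached to both endpoints
  closures <- vector("list", nrow(at))
  for (j in seq_along(back_edges)) {
    bi <- back_edges[j]
    o <- m$bonds$order[bi]; ar <- m$bonds$aromatic[bi]
    btok <- bond_token(o, ar, at$aromatic[m$bonds$a1[bi]], at$aromatic[m$bonds$a2[bi]])
    dg <- if (j < 10) as.character(j) else paste0("%", j)
    lab <- paste0(btok, dg)
    closures[[m$bonds$a1[bi]]] <- c(closures[[m$bonds$a1[bi]]], lab)
    closures[[m$bonds$a2[bi]]] <- c(closures[[m$bonds$a2[bi]]], lab)
  }
  visited[] <- FALSE
  used_bond <- logical(nrow(m$bonds))
  used_bond[back_edges] <- TRUE # exclude back edges from tree traversal
  tree_used <- logical(nrow(m$bonds))
  emit <- function(a, from_bond) {
    visited[a] <<- TRUE
    tok <- ""
    if (!is.null(from_bond)) {
      tok <- bond_token(m$bonds$order[from_bond], m$bonds$aromatic[from_bond],
                        at$aromatic[m$bonds$a1[from_bond]], at$aromatic[m$bonds$a2[from_bond]])
    }
    s <- paste0(tok, atom_token(at$element[a], at$charge[a], at$aromatic[a], at$hcount[a]))
    if (!is.null(closures[[a]])) s <- paste0(s, paste0(closures[[a]], collapse = ""))
    nbs <- nb[[a]]
    if (length(nbs) > 0) nbs <- nbs[order(as.integer(names(nbs)))]
    branches <- character(0)
    for (k in seq_along(nbs)) {
      bi <- nbs[k]; b <- as.integer(names(nbs)[k])
      if (used_bond[bi] || tree_used[bi] || visited[b]) next
      tree_used[bi] <<- TRUE
      branches <- c(branches, emit(b, bi))
    }
    if (length(branches) > 1) {
      s <- paste0(s, paste0("(", branches[-length(branches)], ")", collapse = ""),
                  branches[length(branches)])
    } else if (length(branches) == 1) {
      s <- paste0(s, branches)
    }
    s
  }
  paste(vapply(roots, function(r) emit(r, NULL), character(1)), collapse = ".")
}

## ---- canonical form --------------------------------------------------------

#' Canonical structure string
#'
#' Returns the canonical SMILES of a molecule (Open Babel canonicalization).
#' The output is invariant under atom reordering: two molecules receive the
#' same string exactly when their molecular graphs are identical (within the
#' toolkit's aromaticity model; stereochemistry is ignored). Returns `NA` for
#' graphs Open Babel cannot sanitise (for example unkekulizable aromatic
#' fragments left by ring pruning).
#'
#' @param m An `ncmfp_mol`, or a SMILES string.
#' @return A single string, or `NA_character_`.
#' @export
canonical_form <- function(m) {
  smi <- if (inherits(m, "ncmfp_mol")) write_smiles(m) else as.character(m)
  if (!nzchar(smi)) return(NA_character_)
  out <- ob_convert("SMI", "CAN", paste0(smi, "\n"))
  out <- trimws(sub("[\t ].*$", "", sub("\n.*$", "", out)))
  if (!nzchar(out)) NA_character_ else out
}

## ---- preprocessing (fingerprint step I) ------------------------------------

#' Prepare a molecule for fingerprinting
#'
#' Fingerprint generation starts by adding all missing hydrogen atoms,
#' fixing atomic indices, and computing the molecular weight and Hill-order
#' molecular formula. Heavy atoms keep their parse-time indices; hydrogens are
#' appended after them. The operation is idempotent.
#'
#' @param m An `ncmfp_mol` (output of [parse_structure()]).
#' @return An `ncmfp_prepared` molecule with elements `mw` (Da) and `formula`.
#' @examples
#' p <- preprocess(parse_structure("CCO"))
#' p$mw        # 46.07
#' p$formula   # "C2H6O"
#' @export
preprocess <- function(m) {
  stopifnot(inherits(m, "ncmfp_mol"))
  if (inherits(m, "ncmfp_prepared")) return(m)
  at <- m$atoms; bd <- m$bonds
  unknown <- setdiff(unique(at$element), c(names(ATOMIC_MASS), "H"))
  if (length(unknown) > 0) {
    ncmfp_abort(paste0("Unsupported element(s): ", paste(unknown, collapse = ", ")),
                "ncmfp_prepare_error")
  }
  if (any(at$hcount < 0)) ncmfp_abort("Negative hydrogen count.", "ncmfp_prepare_error")
  n0 <- nrow(at)
  n_h <- sum(at$hcount)
  if (n_h > 0) {
    owner <- rep(seq_len(n0), at$hcount)
    at2 <- tibble::add_row(at,
      element = rep("H", n_h), charge = 0L, aromatic = FALSE, hcount = 0L
    )
    bd2 <- tibble::add_row(bd,
      a1 = owner, a2 = n0 + seq_len(n_h), order = 1L, aromatic = FALSE
    )
  } else {
    at2 <- at; bd2 <- bd
  }
  out <- new_mol(at2, bd2, name = m$name)
  class(out) <- c("ncmfp_prepared", class(out))
  out$mw <- mol_weight(out)
  out$formula <- mol_formula(out)
  out
}

# Molecular weight over heavy atoms; hydrogens are counted through the
# per-atom hcount fields (authoritative also for prepared molecules, whose
# explicit H rows mirror them). Attachment markers weigh nothing.
#' @noRd
mol_weight <- function(m, atom_subset = NULL) {
  at <- if (is.null(atom_subset)) m$atoms else m$atoms[atom_subset, , drop = FALSE]
  at <- at[at$element != "H", , drop = FALSE]
  masses <- ATOMIC_MASS[at$element]
  hmass <- at$hcount * 1.008
  round(sum(masses + hmass), 2)
}

#' @noRd
mol_formula <- function(m) {
  at <- m$atoms[m$atoms$element != "H", , drop = FALSE]
  counts <- table(at$element)
  if ("*" %in% names(counts)) counts <- counts[names(counts) != "*"]
  nh <- sum(at$hcount)
  els <- sort(names(counts))
  # Hill order: C first, H second, rest alphabetical
  ord <- c(intersect("C", els), setdiff(els, "C"))
  if (!"C" %in% els) ord <- els
  parts <- vapply(ord, function(e) {
    n <- counts[[e]]
    paste0(e, if (n > 1) n else "")
  }, character(1))
  h_part <- if (nh > 0) paste0("H", if (nh > 1) nh else "") else ""
  if ("C" %in% els) {
    paste0(parts[1], h_part, paste(parts[-1], collapse = ""))
  } else {
    # no carbon: strictly alphabetical including H
    all_parts <- c(parts, if (nzchar(h_part)) stats::setNames(h_part, "H"))
    paste(all_parts[order(names(all_parts))], collapse = "")
  }
}

## ---- graph utilities -------------------------------------------------------

# induced submolecule on atom indices `keep` (1-based); hydrogens collapsed
# beforehand are untouched; hcount of kept atoms is raised by one per removed
# heavy neighbour (single/aromatic bond) or by the bond order for multiple
# bonds, so the result is a sensible closed-valence structure.
submol <- function(m, keep, fix_h = TRUE) {
  keep <- sort(unique(keep))
  remap <- match(seq_len(n_atoms(m)), keep)
  at <- m$atoms[keep, , drop = FALSE]
  if (fix_h) {
    for (i in seq_len(nrow(m$bonds))) {
      a1 <- m$bonds$a1[i]; a2 <- m$bonds$a2[i]
      in1 <- !is.na(remap[a1]); in2 <- !is.na(remap[a2])
      if (in1 && !in2 && m$atoms$element[a2] != "H") {
        at$hcount[remap[a1]] <- at$hcount[remap[a1]] + m$bonds$order[i]
      }
      if (in2 && !in1 && m$atoms$element[a1] != "H") {
        at$hcount[remap[a2]] <- at$hcount[remap[a2]] + m$bonds$order[i]
      }
    }
  }
  bkeep <- !is.na(remap[m$bonds$a1]) & !is.na(remap[m$bonds$a2])
  bd <- m$bonds[bkeep, , drop = FALSE]
  bd$a1 <- remap[bd$a1]; bd$a2 <- remap[bd$a2]
  new_mol(at, bd, name = m$name)
}

# connected components over heavy atoms; returns list of atom index vectors
mol_components <- function(m) {
  hv <- heavy_idx(m)
  if (length(hv) == 0) return(list())
  bkeep <- m$bonds$a1 %in% hv & m$bonds$a2 %in% hv
  g <- igraph::graph_from_edgelist(
    cbind(match(m$bonds$a1[bkeep], hv), match(m$bonds$a2[bkeep], hv)),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(hv) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lapply(split(seq_along(hv), comp), function(ix) hv[ix])
}

# keep the largest covalent component (atom count, then mass, then first)
largest_component <- function(m) {
  comps <- mol_components(m)
  if (length(comps) <= 1) return(m)
  sizes <- lengths(comps)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    mw <- vapply(comps[best], function(ix) mol_weight(m, ix), numeric(1))
    best <- best[which.max(mw)]
  } else {
    best <- best[1]
  }
  submol(m, comps[[best]], fix_h = FALSE)
}
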