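#' Seeded synthetic compound sets
#'
#' The generator emulates class-structured natural-compound collections at toy
#' scale: each class owns a distinct parent ring system, compounds are built
#' by decorating the class scaffold with small fragments at free valence
#' positions, and a planted activity rule (presence of a marked fragment)
#' defines the active class, optionally corrupted by label noise. All
#' randomness flows from the single spec seed, so datasets are reproducible.
#' These fixtures exercise every pipeline stage; they make no claim to
#' realistic natural-product chemistry.
#'
#' @name synthetic
NULL

RING_CATALOG_RAW <- c(
  benzene     = "c1ccccc1",
  pyridine    = "c1ccncc1",
  thiophene   = "c1ccsc1",
  furan       = "c1ccoc1",
  pyrimidine  = "c1cncnc1",
  piperidine  = "C1CCNCC1",
  cyclohexane = "C1CCCCC1",
  pyrazine    = "c1cnccn1",
  naphthalene = "c1ccc2ccccc2c1",
  indole      = "c1ccc2[nH]ccc2c1",
  quinoline   = "c1ccc2ncccc2c1",
  chromenone  = "O=c1ccc2ccccc2o1"
)

# A compact decoration vocabulary: small enough that an n of a few hundred
# compounds covers the decoration combinatorics (so planted signals are
# recoverable), yet with both mono- and two-atom substituents.
FRAGMENT_POOL_RAW <- c(
  methyl  = "*C",
  hydroxy = "*O",
  amino   = "*N",
  methoxy = "*OC"
)

#' Built-in ring-system catalog
#'
#' Named canonical SMILES of the parent ring systems available to
#' [make_toy_spec()]. The first entries are single heteroaromatic or saturated
#' rings with pairwise distinct level-0 scaffolds; fused bicyclics follow.
#'
#' @return Named character vector of canonical SMILES.
#' @export
ring_catalog <- function() {
  ncmfp_cache("ring_catalog", function() {
    vapply(RING_CATALOG_RAW, canonical_form, character(1))
  })
}

fragment_pool <- function() {
  ncmfp_cache("fragment_pool", function() {
    vapply(FRAGMENT_POOL_RAW, canonical_form, character(1))
  })
}

#' Create a synthetic-data specification
#'
#' Deterministically derives, from `(n_classes, seed)`, a set of class parent
#' ring systems (the first `n_classes` catalog entries, so class ring systems
#' are pairwise distinct), a shuffled fragment pool, and a planted activity
#' rule: a compound is active when the rule fragment is attached to its class
#' scaffold (at the rule position, if one is set; by default any position).
#'
#' @param n_classes Number of compound classes (1 to the catalog size).
#' @param seed Integer seed; drives fragment assignment and the rule choice.
#' @param noise_rate Probability of flipping an activity label (default 0).
#' @param rule_position Optional 0-based scaffold position restricting the
#'   planted rule (default `NULL`: any position).
#' @return A `toy_spec` list.
#' @export
make_toy_spec <- function(n_classes, seed, noise_rate = 0, rule_position = NULL) {
  catalog <- ring_catalog()
  if (n_classes < 1 || n_classes > length(catalog)) {
    ncmfp_abort(
      sprintf("`n_classes` must be between 1 and %d.", length(catalog)),
      "ncmfp_input_error"
    )
  }
  stopifnot(noise_rate >= 0, noise_rate <= 1)
  pool <- fragment_pool()
  drawn <- withr::with_seed(as.integer(seed), {
    list(
      pool = sample(pool),
      rule_fragment = sample(pool, 1)
    )
  })
  structure(
    list(
      classes = tibble::tibble(
        class = names(catalog)[seq_len(n_classes)],
        scaffold = unname(catalog[seq_len(n_classes)])
      ),
      fragment_pool = drawn$pool,
      planted_rule = list(
        fragment = unname(drawn$rule_fragment),
        position = rule_position
      ),
      noise_rate = noise_rate,
      seed = as.integer(seed)
    ),
    class = "toy_spec"
  )
}

#' @export
print.toy_spec <- function(x, ...) {
  cat(sprintf(
    "<toy_spec> %d class(es), rule: fragment %s%s, noise %.2f, seed %d\n",
    nrow(x$classes), x$planted_rule$fragment,
    if (is.null(x$planted_rule$position)) "" else
      paste0(" @ position ", x$planted_rule$position),
    x$noise_rate, x$seed
  ))
  invisible(x)
}

#' Attach fragments to a scaffold
#'
#' Builds a molecule by bonding marked fragments to scaffold atoms. Positions
#' are 0-based indices into the scaffold's canonical atom ordering and must
#' have a free valence (an implicit hydrogen to displace).
#'
#' @param scaffold Scaffold canonical SMILES or `ncmfp_mol`.
#' @param fragments Character vector of fragment SMILES, each containing
#'   exactly one `*` attachment marker.
#' @param positions Integer vector of 0-based scaffold atom positions, same
#'   length as `fragments`.
#' @return Canonical SMILES of the decorated molecule.
#' @examples
#' decorate("c1ccccc1", "*C", 0) # toluene
#' @export
decorate <- function(scaffold, fragments = character(0), positions = integer(0)) {
  if (length(fragments) != length(positions)) {
    ncmfp_abort("`fragments` and `positions` must have equal length.",
                "ncmfp_input_error")
  }
  m <- if (is.character(scaffold)) scaffold_mol(scaffold) else scaffold
  atoms <- m$atoms; bonds <- m$bonds
  for (k in seq_along(fragments)) {
    pos <- as.integer(positions[k]) + 1L
    if (pos < 1 || pos > nrow(atoms) || atoms$element[pos] == "H") {
      ncmfp_abort(sprintf("Position %d is not a scaffold atom.", positions[k]),
                  "ncmfp_input_error")
    }
    fm <- parse_structure(fragments[k])
    marker <- which(fm$atoms$element == "*")
    if (length(marker) != 1) {
      ncmfp_abort("Fragments must carry exactly one `*` marker.",
                  "ncmfp_input_error")
    }
    mb <- which(fm$bonds$a1 == marker | fm$bonds$a2 == marker)
    if (length(mb) != 1) {
      ncmfp_abort("Fragment marker must have exactly one bond.",
                  "ncmfp_input_error")
    }
    bond_order <- fm$bonds$order[mb]
    if (atoms$hcount[pos] < bond_order) {
      ncmfp_abort(
        sprintf("No free valence at position %d.", positions[k]),
        "ncmfp_valence_error"
      )
    }
    anchor_frag <- setdiff(c(fm$bonds$a1[mb], fm$bonds$a2[mb]), marker)
    keep <- setdiff(seq_len(nrow(fm$atoms)), marker)
    offset <- nrow(atoms)
    remap <- match(seq_len(nrow(fm$atoms)), keep) + offset
    atoms <- dplyr::bind_rows(atoms, fm$atoms[keep, ])
    atoms$hcount[pos] <- atoms$hcount[pos] - bond_order
    fb <- fm$bonds[-mb, , drop = FALSE]
    if (nrow(fb) > 0) {
      fb$a1 <- remap[fb$a1]; fb$a2 <- remap[fb$a2]
      bonds <- dplyr::bind_rows(bonds, fb)
    }
    bonds <- tibble::add_row(bonds,
      a1 = pos, a2 = remap[anchor_frag],
      order = bond_order, aromatic = FALSE
    )
  }
  out <- new_mol(atoms, bonds)
  cf <- canonical_form(out)
  if (is.na(cf)) {
    ncmfp_abort("Decorated structure failed canonicalization.", "ncmfp_input_error")
  }
  cf
}

#' Evaluate the planted activity rule on structures
#'
#' Decides activity directly from each structure: the molecule is decomposed
#' against its class scaffold and the rule fragment (and position, if the rule
#' fixes one) is looked for among the attachments.
#'
#' @param spec A `toy_spec`.
#' @param compounds A compound table with `class` and `mol`/`smiles` columns.
#' @return Logical vector: rule satisfied.
#' @export
eval_planted_rule <- function(spec, compounds) {
  compounds <- tibble::as_tibble(compounds)
  mols <- compound_mols(compounds)
  scaffold_of <- stats::setNames(spec$classes$scaffold, spec$classes$class)
  vapply(seq_along(mols), function(i) {
    smi <- scaffold_of[[as.character(compounds$class[i])]]
    sc <- tibble::tibble(smiles = smi, mol = list(scaffold_mol(smi)))
    dec <- ncmfp_decompose(preprocess(mols[[i]]), sc)
    att <- dec$attachments
    if (nrow(att) == 0) return(FALSE)
    hit <- att$fragment == spec$planted_rule$fragment & !is.na(att$fragment)
    if (!is.null(spec$planted_rule$position)) {
      hit <- hit & att$position == spec$planted_rule$position
    }
    any(hit)
  }, logical(1))
}

#' Generate a synthetic labelled dataset
#'
#' Produces `n` decorated, ring-containing molecules with class labels
#' (balanced to within one compound), structure-derived activity under the
#' spec's planted rule XOR Bernoulli(noise), and IC50 values consistent with
#' the activity threshold (actives below, inactives above 10 micromolar).
#'
#' @param spec A `toy_spec`.
#' @param n Number of compounds (>= 1).
#' @return A tibble with columns `id`, `smiles`, `mol`, `class`, `rule_truth`,
#'   `activity`, `label`, `ic50`, plus bookkeeping columns `frag_set` and
#'   `pos_set` (list columns of what was attached where).
#' @export
generate_dataset <- function(spec, n) {
  stopifnot(inherits(spec, "toy_spec"), n >= 1)
  pool <- spec$fragment_pool
  rule_frag <- spec$planted_rule$fragment
  rule_pos <- spec$planted_rule$position
  classes <- spec$classes

  rows <- withr::with_seed(spec$seed + 1L, {
    lapply(seq_len(n), function(i) {
      cl <- classes$class[(i - 1L) %% nrow(classes) + 1L]
      scaffold <- classes$scaffold[classes$class == cl]
      sm <- scaffold_mol(scaffold)
      free <- which(sm$atoms$hcount > 0) - 1L
      target_active <- stats::rbinom(1, 1, 0.5) == 1
      # at most one incidental decoration: the planted fragment stays the
      # dominant structural difference between actives and inactives
      others <- setdiff(pool, rule_frag)
      extras <- others[sample.int(length(others), sample(0:1, 1))]
      frags <- if (target_active) c(rule_frag, extras) else extras
      k <- min(length(frags), length(free))
      frags <- frags[seq_len(k)]
      pos <- if (target_active && !is.null(rule_pos)) {
        rest <- setdiff(free, rule_pos)
        c(rule_pos, rest[sample.int(length(rest), k - 1L)])
      } else if (k > 0) {
        free[sample.int(length(free), k)]
      } else {
        integer(0)
      }
      smi <- decorate(scaffold, frags, pos)
      tibble::tibble(
        id = sprintf("toy_%04d", i), smiles = smi, class = cl,
        frag_set = list(frags), pos_set = list(pos)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  out$mol <- lapply(out$smiles, parse_structure)
  out$rule_truth <- eval_planted_rule(spec, out)
  flips <- withr::with_seed(
    spec$seed + 2L,
    stats::rbinom(n, 1, spec$noise_rate) == 1
  )
  active <- xor(out$rule_truth, flips)
  out$activity <- ifelse(active, "active", "inactive")
  out$label <- out$activity
  out$ic50 <- withr::with_seed(
    spec$seed + 3L,
    ifelse(active, stats::runif(n, 0.5, 9.5), stats::runif(n, 10.5, 99.5))
  )
  out[, c("id", "smiles", "mol", "class", "rule_truth", "activity",
          "label", "ic50", "frag_set", "pos_set")]
}
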