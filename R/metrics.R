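#' Scaffold-library diagnostics
#'
#' Two diagnostics guide the choice of scaffold levels: database coverage
#' (the fraction of a compound database matched by the scaffolds of a given
#' level, decomposed by class) and the class-assignment heat map (how often
#' compounds of class i are assigned to class j by scaffold matching).
#' Coverage assigns each compound to at most one class; the heat map by
#' default lets a compound count towards every class whose scaffolds match it.
#'
#' @name library-metrics
NULL

# match a compound against every (class, level) cell of a library;
# returns tibble(class, level) of cells with at least one matching scaffold
match_cells <- function(mol, lib_mols) {
  tg <- mol_graph_heavy(mol)
  tcount <- table(tg$element)
  hits <- logical(nrow(lib_mols))
  for (i in seq_len(nrow(lib_mols))) {
    pm <- lib_mols$mol[[i]]
    pg <- mol_graph_heavy(pm)
    if (length(pg$element) > length(tg$element)) next
    pcount <- table(pg$element)
    if (any(!names(pcount) %in% names(tcount)) ||
        any(pcount > tcount[names(pcount)])) next
    hits[i] <- length(match_heavy(pg, tg)) > 0
  }
  lib_mols[hits, c("class", "level", "n_rings")]
}

lib_with_mols <- function(lib, levels) {
  sc <- lib$scaffolds[lib$scaffolds$level %in% levels, , drop = FALSE]
  sc$mol <- lapply(sc$smiles, scaffold_mol)
  sc
}

#' Database coverage of a scaffold library
#'
#' For each requested level m, the fraction of database compounds containing
#' at least one level-m scaffold as a substructure. A compound matching the
#' scaffolds of several classes is counted in exactly one: the class whose
#' matched scaffold has the largest ring count, ties broken by library class
#' order. The per-class fractions sum to the level's total coverage.
#'
#' @param db A compound table (`mol` or `smiles` column), e.g. from
#'   [read_compound_set()].
#' @param lib A `scaffold_library`.
#' @param levels Scaffold levels to evaluate (default: all levels in `lib`).
#' @return An `ncmfp_coverage` tibble with one row per (level, class):
#'   `n_matched` and `fraction`; `attr(, "total")` holds per-level totals.
#' @export
db_coverage <- function(db, lib, levels = NULL) {
  stopifnot(inherits(lib, "scaffold_library"))
  db <- tibble::as_tibble(db)
  if (nrow(db) == 0) ncmfp_abort("Empty compound database.", "ncmfp_input_error")
  if (is.null(levels)) levels <- lib$levels
  missing_lv <- setdiff(levels, unique(lib$scaffolds$level))
  if (length(missing_lv) > 0) {
    ncmfp_abort(paste0("Library has no scaffolds at level(s) ",
                       paste(missing_lv, collapse = ", ")), "ncmfp_input_error")
  }
  mols <- compound_mols(db)
  lm <- lib_with_mols(lib, levels)
  n <- length(mols)
  class_rank <- stats::setNames(seq_along(lib$classes), lib$classes)

  assigned <- list()
  for (i in seq_len(n)) {
    cells <- match_cells(mols[[i]], lm)
    if (nrow(cells) == 0) next
    for (lv in unique(cells$level)) {
      cl <- cells[cells$level == lv, , drop = FALSE]
      # one class only: largest matched ring count, then class order
      cl <- cl[order(-cl$n_rings, class_rank[cl$class]), , drop = FALSE]
      assigned[[length(assigned) + 1L]] <- tibble::tibble(
        level = lv, class = cl$class[1]
      )
    }
  }
  counts <- if (length(assigned) > 0) {
    dplyr::count(dplyr::bind_rows(assigned), .data$level, .data$class,
                 name = "n_matched")
  } else {
    tibble::tibble(level = integer(0), class = character(0), n_matched = integer(0))
  }
  grid <- tidyr::expand_grid(level = sort(levels), class = lib$classes)
  out <- dplyr::left_join(grid, counts, by = c("level", "class"))
  out$n_matched <- dplyr::coalesce(out$n_matched, 0L)
  out$fraction <- out$n_matched / n
  total <- dplyr::summarise(
    dplyr::group_by(out, .data$level),
    n_matched = sum(.data$n_matched),
    coverage = sum(.data$fraction), .groups = "drop"
  )
  total$n <- n
  out <- tibble::new_tibble(out, class = "ncmfp_coverage", total = total, n = n)
  out
}

#' Per-level total coverage
#' @param x An `ncmfp_coverage` table.
#' @export
coverage_total <- function(x) attr(x, "total")

#' Plot coverage against scaffold level
#' @param object An `ncmfp_coverage` table.
#' @param ... Unused.
#' @method autoplot ncmfp_coverage
#' @export
autoplot.ncmfp_coverage <- function(object, ...) {
  d <- coverage_total(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$coverage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "scaffold level", y = "DB coverage") +
    ggplot2::theme_minimal()
}

#' Class-assignment heat map
#'
#' For class-labelled compounds, counts how often a compound of true class i
#' is assigned to class j because some level-m scaffold of class j matches it.
#' Cell (i, j) is the fraction of class-i compounds assigned to class j; the
#' diagonal is the correct-assignment rate. With `multi_assign = TRUE`
#' (default) a compound contributes to every matching class, so rows need not
#' sum to 1 and the matrix is generally asymmetric; with `multi_assign =
#' FALSE` the coverage dedup rule (largest matched scaffold, then class order)
#' assigns each compound to a single class. An ideal library has diagonal 1
#' and off-diagonal 0.
#'
#' @param labeled A compound table with `class` labels (all present in `lib`).
#' @param lib A `scaffold_library`.
#' @param level The scaffold level to evaluate.
#' @param multi_assign Count a compound in every matching class (default) or
#'   apply the single-class rule.
#' @return An `ncmfp_heatmap` tibble with columns `true_class`,
#'   `assigned_class`, `n`, `proportion`.
#' @export
classification_heatmap <- function(labeled, lib, level, multi_assign = TRUE) {
  stopifnot(inherits(lib, "scaffold_library"))
  labeled <- tibble::as_tibble(labeled)
  if (!"class" %in% names(labeled)) {
    ncmfp_abort("Compound table needs a `class` column.", "ncmfp_label_error")
  }
  unknown <- setdiff(unique(labeled$class), lib$classes)
  if (length(unknown) > 0) {
    ncmfp_abort(paste0("Class label(s) not in library: ",
                       paste(unknown, collapse = ", ")), "ncmfp_label_error")
  }
  mols <- compound_mols(labeled)
  lm <- lib_with_mols(lib, level)
  class_rank <- stats::setNames(seq_along(lib$classes), lib$classes)

  rows <- list()
  for (i in seq_along(mols)) {
    cells <- match_cells(mols[[i]], lm)
    if (nrow(cells) == 0) next
    hit_classes <- if (multi_assign) {
      unique(cells$class)
    } else {
      cells <- cells[order(-cells$n_rings, class_rank[cells$class]), , drop = FALSE]
      cells$class[1]
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      true_class = as.character(labeled$class[i]), assigned_class = hit_classes
    )
  }
  class_n <- dplyr::count(
    tibble::tibble(true_class = as.character(labeled$class)),
    .data$true_class, name = "n_class"
  )
  counts <- if (length(rows) > 0) {
    dplyr::count(dplyr::bind_rows(rows), .data$true_class, .data$assigned_class)
  } else {
    tibble::tibble(true_class = character(0), assigned_class = character(0),
                   n = integer(0))
  }
  grid <- tidyr::expand_grid(
    true_class = lib$classes, assigned_class = lib$classes
  )
  out <- dplyr::left_join(grid, counts, by = c("true_class", "assigned_class"))
  out$n <- dplyr::coalesce(out$n, 0L)
  out <- dplyr::left_join(out, class_n, by = "true_class")
  out$n_class <- dplyr::coalesce(out$n_class, 0L)
  out$proportion <- ifelse(out$n_class == 0, 0, out$n / out$n_class)
  out$n_class <- NULL
  tibble::new_tibble(out, class = "ncmfp_heatmap", level = level,
                     multi_assign = multi_assign)
}

#' Heat map as a matrix (true classes in rows)
#' @param x An `ncmfp_heatmap` table.
#' @export
heatmap_matrix <- function(x) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(x)[, c("true_class", "assigned_class", "proportion")],
    names_from = "assigned_class", values_from = "proportion"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$true_class
  m
}

#' Plot a class-assignment heat map
#' @param object An `ncmfp_heatmap` table.
#' @param ... Unused.
#' @method autoplot ncmfp_heatmap
#' @export
autoplot.ncmfp_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$assigned_class, y = .data$true_class, fill = .data$proportion
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "assigned class", y = "true class",
                  fill = "proportion") +
    ggplot2::theme_minimal()
}

#' Write coverage / heat-map tables as TSV
#' @param x An `ncmfp_coverage` or `ncmfp_heatmap` table.
#' @param path Output file.
#' @export
write_metric_tsv <- function(x, path) {
  utils::write.table(tibble::as_tibble(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
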