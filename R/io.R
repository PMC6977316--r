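#' Read a compound set with the ring filter
#'
#' Reads compounds from a SMILES file (`SMILES<TAB>id` or whitespace
#' separated), an SDF (V2000) file, or a delimited table with header columns
#' `id`, `smiles` and optionally `class`, `ic50`, `activity`. Multi-fragment
#' records (salts) are reduced to their largest covalent component before
#' filtering. Records that fail to parse are skipped with a warning; acyclic
#' compounds are excluded and counted separately: every returned record
#' contains at least one ring.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"smiles"`, `"sdf"`, `"csv"`, `"tsv"`.
#' @return A tibble with columns `id`, `smiles` (canonical form of the kept
#'   component), `mol` (list of `ncmfp_mol`) and, when present in the input,
#'   `class`, `ic50`, `activity`. Attributes `n_input`, `n_malformed` and
#'   `n_acyclic` record the filtering bookkeeping.
#' @export
read_compound_set <- function(path, format = c("auto", "smiles", "sdf", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    ncmfp_abort(paste0("File not found: ", path), "ncmfp_io_error")
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      smi = , smiles = "smiles", sdf = , mol = "sdf",
      csv = "csv", tsv = , txt = "tsv",
      "smiles"
    )
  }
  recs <- switch(format,
    smiles = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(trimws(lines), "\\s+")
      tibble::tibble(
        id = vapply(seq_along(parts), function(i) {
          if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("record_", i)
        }, character(1)),
        input = vapply(parts, `[[`, character(1), 1)
      )
    },
    sdf = {
      txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
      blocks <- strsplit(txt, "\\$\\$\\$\\$")[[1]]
      blocks <- blocks[nzchar(trimws(blocks))]
      tibble::tibble(
        id = vapply(seq_along(blocks), function(i) {
          ti <- trimws(strsplit(blocks[i], "\n")[[1]][1])
          if (is.na(ti) || !nzchar(ti)) paste0("record_", i) else ti
        }, character(1)),
        input = paste0(blocks, "\n$$$$\n")
      )
    },
    csv = ,
    tsv = {
      tab <- utils::read.table(
        path, header = TRUE, sep = if (format == "csv") "," else "\t",
        stringsAsFactors = FALSE, comment.char = "", quote = "\""
      )
      names(tab) <- tolower(names(tab))
      if (!all(c("id", "smiles") %in% names(tab))) {
        ncmfp_abort("Delimited input needs `id` and `smiles` columns.", "ncmfp_io_error")
      }
      out <- tibble::tibble(id = as.character(tab$id), input = tab$smiles)
      for (extra in c("class", "ic50", "activity")) {
        if (extra %in% names(tab)) out[[extra]] <- tab[[extra]]
      }
      out
    }
  )
  struct_format <- if (format == "sdf") "sdf" else "smiles"

  n_input <- nrow(recs)
  malformed <- character(0)
  acyclic <- character(0)
  rows <- vector("list", n_input)
  for (i in seq_len(n_input)) {
    m <- tryCatch(
      parse_structure(recs$input[i], format = struct_format, id = recs$id[i]),
      error = function(e) NULL
    )
    if (is.null(m)) {
      malformed <- c(malformed, recs$id[i])
      next
    }
    m <- largest_component(m)
    if (ring_count(m) < 1) {
      acyclic <- c(acyclic, recs$id[i])
      next
    }
    cf <- canonical_form(m)
    if (is.na(cf)) {
      malformed <- c(malformed, recs$id[i])
      next
    }
    rows[[i]] <- tibble::tibble(id = recs$id[i], smiles = cf, mol = list(m))
  }
  out <- dplyr::bind_rows(rows)
  if (length(malformed) > 0) {
    ncmfp_warn(sprintf(
      "Skipped %d malformed record(s): %s", length(malformed),
      paste(utils::head(malformed, 10), collapse = ", ")
    ), class = "ncmfp_skip_warning")
  }
  if (length(acyclic) > 0) {
    ncmfp_warn(sprintf(
      "Excluded %d acyclic compound(s): %s", length(acyclic),
      paste(utils::head(acyclic, 10), collapse = ", ")
    ), class = "ncmfp_ring_filter_warning")
  }
  if (nrow(out) == 0) {
    ncmfp_warn("No compounds survived parsing and the ring filter.",
               class = "ncmfp_empty_warning")
    out <- tibble::tibble(id = character(0), smiles = character(0), mol = list())
  } else {
    for (extra in c("class", "ic50", "activity")) {
      if (extra %in% names(recs)) {
        out[[extra]] <- recs[[extra]][match(out$id, recs$id)]
      }
    }
  }
  attr(out, "n_input") <- n_input
  attr(out, "n_malformed") <- length(malformed)
  attr(out, "n_acyclic") <- length(acyclic)
  out
}
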