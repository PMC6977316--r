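# Internal helpers shared across the package.

the <- new.env(parent = emptyenv())

#' @noRd
ncmfp_cache <- function(key, value_fn) {
  if (is.null(the$cache)) the$cache <- new.env(parent = emptyenv())
  if (!exists(key, envir = the$cache, inherits = FALSE)) {
    assign(key, value_fn(), envir = the$cache)
  }
  get(key, envir = the$cache, inherits = FALSE)
}

#' @noRd
clear_ncmfp_cache <- function() {
  the$cache <- new.env(parent = emptyenv())
  invisible(NULL)
}

# Average atomic masses (2 dp beyond the common elements is immaterial for
# fragment ordering; values are IUPAC standard atomic weights).
ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.086, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  Se = 78.971, Br = 79.904, As = 74.922, I = 126.904, Li = 6.94, `*` = 0
)

# Elements written lowercase in SMILES when aromatic.
AROMATIC_ELEMENTS <- c("B", "C", "N", "O", "P", "S", "Se", "As")

#' @noRd
ncmfp_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "ncmfp_error"), ...)
}

#' @noRd
ncmfp_warn <- function(message, class = "ncmfp_warning", ...) {
  rlang::warn(message, class = class, ...)
}
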