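#' Simulated cell classes and default channel panel
#'
#' `cell_classes()` returns the seven mutually exclusive ground-truth labels
#' used throughout the package: `beta` (INS+NKX6.1+), `alpha_poly` (GCG+
#' alpha and GCG+INS+ polyhormonal cells lacking NKX6.1), `delta` (SST+),
#' `ec_like` (serotonin+ enterochromaffin-like), `ductal` (CFTR-expressing
#' ductal-like), `progenitor` (NKX6.1+NEUROG3+ endocrine progenitors) and
#' `other`. `sc_channels()` returns the default antibody panel: the two
#' sorting channels (CD133, CD49a) plus the identity markers used to define
#' the classes.
#'
#' @return A character vector of class labels or channel names.
#' @examples
#' cell_classes()
#' sc_channels()
#' @export
cell_classes <- function() {
  c("beta", "alpha_poly", "delta", "ec_like", "ductal", "progenitor", "other")
}

#' @rdname cell_classes
#' @export
sc_channels <- function() {
  c("CD133", "CD49a", "INS", "NKX6.1", "GCG", "NEUROG3", "SST",
    "SEROTONIN", "CFTR")
}

# endocrine classes in the CD49a-positive sense (ITGA1 pan-endocrine,
# absent from ductal epithelium)
endocrine_classes <- function() c("beta", "alpha_poly", "delta", "ec_like")

assert_cell_class <- function(x, arg = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || !(x %in% cell_classes())) {
    stop(sprintf("`%s` must be one of: %s", arg,
                 paste(cell_classes(), collapse = ", ")), call. = FALSE)
  }
  x
}
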