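#' Write a gating report
#'
#' JSON is the canonical machine format: fixed key order, compositions as
#' fractions in \[0,1\] (never percentages), floats at 9 significant
#' digits, `null` compositions when the corresponding table was empty. The
#' TSV flattening carries one row per cell class with its pre/post
#' fractions and enrichment fold.
#'
#' @param report A [gating_report()].
#' @param path Output file.
#' @param format `"json"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @examples
#' tab <- simulate_events(default_sc_islet_config(), 500, timepoint = 7)
#' f <- tempfile(fileext = ".json")
#' write_report(gating_report(tab, dual_sort_gates()), f)
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  stopifnot(inherits(report, "gating_report"))
  format <- match.arg(format)
  comp_or_null <- function(comp) {
    if (comp$n == 0L) NULL else as.list(signif(comp$fractions, 9))
  }
  if (format == "json") {
    obj <- list(
      gates_applied = report$gates_applied,
      n_in = report$n_in,
      n_out = report$n_out,
      yield_fraction = signif(report$yield_fraction, 9),
      composition_in = comp_or_null(report$composition_in),
      composition_out = comp_or_null(report$composition_out),
      enrichment = as.list(signif(report$enrichment, 9)))
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                             na = "null", digits = NA, pretty = TRUE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con, sep = "\n", useBytes = TRUE)
  } else {
    fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.9g", x))
    lines <- c(
      "class\tfraction_in\tfraction_out\tenrichment_fold",
      sprintf("%s\t%s\t%s\t%s", cell_classes(),
              fmt(report$composition_in$fractions),
              fmt(report$composition_out$fractions),
              fmt(report$enrichment)))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a gating report written as JSON
#'
#' Inverse of [write_report()] for the JSON format; counts round-trip
#' exactly.
#'
#' @param path JSON report file.
#' @return A `gating_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_comp <- function(fracs, n) {
    fractions <- if (is.null(fracs)) {
      setNames(rep(NA_real_, length(cell_classes())), cell_classes())
    } else {
      unlist(fracs)[cell_classes()]
    }
    structure(list(fractions = fractions, n = n), class = "composition")
  }
  structure(
    list(gates_applied = obj$gates_applied,
         n_in = as.integer(obj$n_in), n_out = as.integer(obj$n_out),
         composition_in = as_comp(obj$composition_in, as.integer(obj$n_in)),
         composition_out = as_comp(obj$composition_out,
                                   as.integer(obj$n_out)),
         yield_fraction = as.numeric(obj$yield_fraction),
         enrichment = {
           e <- unlist(obj$enrichment)[cell_classes()]
           names(e) <- cell_classes()
           vapply(e, function(v) if (is.null(v)) NA_real_ else v, numeric(1))
         }),
    class = "gating_report")
}

#' Serialize simulation configurations and gate lists as JSON
#'
#' `write_sim_config()`/`read_sim_config()` round-trip a [sim_config()]
#' (keys: `weights`, `channel_models`, `drifts`, `seed`).
#' `write_gates()`/`read_gates()` round-trip an ordered list of
#' [gate_spec] objects, each serialized with its `kind`, `channel` and the
#' fields its kind requires.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_sim_config(default_sc_islet_config(), f)
#' cfg <- read_sim_config(f)
#' cfg$weights
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- list(weights = as.list(config$weights),
              channel_models = config$channel_models,
              drifts = config$drifts,
              seed = config$seed)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  drifts <- obj$drifts
  if (is.null(drifts) || !length(drifts)) drifts <- NULL
  sim_config(weights = unlist(obj$weights),
             channel_models = obj$channel_models,
             drifts = drifts,
             seed = obj$seed)
}

#' @rdname write_sim_config
#' @param gates Ordered list of [gate_spec] objects.
#' @export
write_gates <- function(gates, path) {
  stopifnot(is.list(gates), all(vapply(gates, inherits, logical(1),
                                       "gate_spec")))
  obj <- lapply(gates, function(g) {
    out <- list(kind = g$kind, channel = g$channel)
    if (g$kind == "top_fraction") out$fraction <- g$fraction
    if (g$kind == "threshold") {
      out$cutoff <- g$cutoff
      out$direction <- g$direction
    }
    if (g$kind == "positive_split" && !is.null(g$cutoff)) {
      out$cutoff <- g$cutoff
    }
    out
  })
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_gates <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(obj, function(g) {
    switch(g$kind,
      top_fraction = gate_top_fraction(g$channel, g$fraction),
      threshold = gate_threshold(g$channel, g$cutoff, g$direction),
      positive_split = gate_positive_split(g$channel, g$cutoff),
      stop(sprintf("unknown gate kind '%s'", g$kind), call. = FALSE))
  })
}
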