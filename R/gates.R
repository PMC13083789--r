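#' Gate specifications
#'
#' Declarative, composable gates on a single channel, mirroring what a cell
#' sorter does:
#' \describe{
#'   \item{`gate_top_fraction(channel, fraction)`}{keeps the brightest
#'     `ceiling(fraction * n)` events — rank-based, so the selected count is
#'     exact regardless of ties (ties broken by descending intensity, then
#'     original event order). This is the "CD133-high" gate; the sorting
#'     protocol sets it to the top 20\%.}
#'   \item{`gate_threshold(channel, cutoff, direction)`}{keeps events
#'     strictly above (or below) a fixed linear-scale intensity cutoff.}
#'   \item{`gate_positive_split(channel, cutoff = NULL)`}{keeps the positive
#'     mode of a bimodal channel. With `cutoff = NULL` the split is found
#'     automatically: sort the log10 intensities, cut at the largest
#'     consecutive gap, and place the threshold at the midpoint of the two
#'     cluster means (log10 scale) — a deterministic operationalization of
#'     "clear separation from the negative population", as used for CD49a.
#'     A manual linear-scale `cutoff` overrides the heuristic.}
#' }
#'
#' @param channel Channel the gate acts on.
#' @param fraction Fraction in (0, 1\] of events to keep (top-fraction gate).
#' @param cutoff Linear-scale intensity cutoff.
#' @param direction `"above"` (default) or `"below"` (threshold gate).
#' @return An object of class `gate_spec`.
#' @examples
#' gate_top_fraction("CD133", 0.20)
#' gate_positive_split("CD49a")
#' @name gate_spec
NULL

#' @rdname gate_spec
#' @export
gate_top_fraction <- function(channel, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  new_gate("top_fraction", channel, fraction = fraction)
}

#' @rdname gate_spec
#' @export
gate_threshold <- function(channel, cutoff, direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  new_gate("threshold", channel, cutoff = cutoff, direction = direction)
}

#' @rdname gate_spec
#' @export
gate_positive_split <- function(channel, cutoff = NULL) {
  if (!is.null(cutoff)) stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  new_gate("positive_split", channel, cutoff = cutoff)
}

new_gate <- function(kind, channel, ...) {
  stopifnot(is.character(channel), length(channel) == 1L)
  structure(list(kind = kind, channel = channel, ...), class = "gate_spec")
}

describe_gate <- function(gate) {
  switch(gate$kind,
    top_fraction = sprintf("top %.4g%% on %s", 100 * gate$fraction,
                           gate$channel),
    threshold = sprintf("%s %s %.6g", gate$channel,
                        if (gate$direction == "above") ">" else "<",
                        gate$cutoff),
    positive_split = if (is.null(gate$cutoff)) {
      sprintf("%s positive (auto split)", gate$channel)
    } else {
      sprintf("%s positive (cutoff %.6g)", gate$channel, gate$cutoff)
    })
}

#' @export
print.gate_spec <- function(x, ...) {
  cat("<gate_spec>", describe_gate(x), "\n")
  invisible(x)
}

#' Intensity cutoff of a top-fraction gate
#'
#' Returns the intensity of the `ceiling(fraction * n)`-th largest event.
#' Downstream selection is rank-based (exactly that many events are kept,
#' ties broken by descending intensity then original order), so the cutoff
#' is reported for display and instrument transfer, not used for selection.
#'
#' @param intensities Non-empty numeric vector.
#' @param fraction Fraction in (0, 1\].
#' @return Single intensity value.
#' @examples
#' top_fraction_threshold(c(1, 5, 3, 9), 0.5)  # 5
#' @export
top_fraction_threshold <- function(intensities, fraction) {
  if (!length(intensities)) {
    stop("cannot compute a top-fraction cutoff on an empty table",
         call. = FALSE)
  }
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  k <- ceiling(fraction * length(intensities))
  sort(intensities, decreasing = TRUE)[k]
}

# Rank-based top-fraction selection: indices of the k brightest events,
# ties broken by descending intensity then original event order. Returned
# in original-order so the sub-table preserves event order.
top_fraction_indices <- function(intensities, fraction) {
  k <- ceiling(fraction * length(intensities))
  ord <- order(-intensities, seq_along(intensities))
  sort(ord[seq_len(k)])
}

# Largest-gap split on log10 intensities; returns the log10 threshold
# (midpoint of the two cluster means). Fewer than 2 events: no split is
# identifiable, everything is called positive (-Inf threshold).
positive_split_log10_cutoff <- function(intensities) {
  if (length(intensities) < 2L) return(-Inf)
  s <- sort(log10(intensities))
  gaps <- diff(s)
  i <- which.max(gaps)  # first maximum: deterministic under tied gaps
  (mean(s[seq_len(i)]) + mean(s[-seq_len(i)])) / 2
}
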