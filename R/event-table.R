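#' Event tables: per-cell intensity matrices
#'
#' An `event_table` is the universal currency of the pipeline: one row per
#' cell (event), one column per fluorescence channel, all intensities on the
#' positive linear scale. Tables optionally carry per-event ground-truth
#' class labels (see [cell_classes()]), a stage-6 day (`timepoint`), and
#' free-form metadata (used, among other things, to record gate provenance).
#' Every event has a stable integer `event_id` assigned at creation and
#' preserved through gating, so post-sort tables can be checked to be
#' subsets of their input.
#'
#' @param intensities Numeric matrix, `n_events x n_channels`, with channel
#'   names as column names; all values must be strictly positive.
#' @param labels Optional character/factor vector of length `n_events` with
#'   values from [cell_classes()], or `NULL` when ground truth is withheld.
#' @param timepoint Optional single non-negative integer: the stage-6 day.
#' @param event_id Optional integer vector of unique event identifiers;
#'   defaults to `1:n_events`.
#' @param metadata Named list of free-form provenance.
#'
#' @return An object of class `event_table`.
#' @examples
#' m <- matrix(10^rnorm(20, 2), ncol = 2,
#'             dimnames = list(NULL, c("CD133", "CD49a")))
#' tab <- event_table(m, labels = rep(c("beta", "ductal"), 5), timepoint = 7)
#' n_events(tab)
#' channel_names(tab)
#' @export
event_table <- function(intensities, labels = NULL, timepoint = NULL,
                        event_id = NULL, metadata = list()) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(colnames(intensities))) {
    stop("`intensities` must have channel names as column names",
         call. = FALSE)
  }
  n <- nrow(intensities)
  if (n > 0L && (anyNA(intensities) || any(intensities <= 0))) {
    bad <- which(is.na(intensities) | intensities <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "intensities must be strictly positive; offending value at row %d, channel '%s'",
      bad[["row"]], colnames(intensities)[bad[["col"]]]), call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) {
      stop(sprintf("labels has length %d but table has %d events",
                   length(labels), n), call. = FALSE)
    }
    unknown <- setdiff(unique(labels), cell_classes())
    if (length(unknown)) {
      stop(sprintf("unknown cell class label(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    labels <- factor(labels, levels = cell_classes())
  }
  if (!is.null(timepoint)) {
    timepoint <- as.integer(timepoint)
    stopifnot(length(timepoint) == 1L, !is.na(timepoint), timepoint >= 0L)
  }
  if (is.null(event_id)) {
    event_id <- seq_len(n)
  } else {
    event_id <- as.integer(event_id)
    if (length(event_id) != n || anyDuplicated(event_id)) {
      stop("event_id must be unique and one per event", call. = FALSE)
    }
  }
  structure(
    list(intensities = intensities, labels = labels, timepoint = timepoint,
         event_id = event_id, metadata = metadata),
    class = "event_table")
}

#' @rdname event_table
#' @param table An `event_table`.
#' @export
n_events <- function(table) {
  stopifnot(inherits(table, "event_table"))
  nrow(table$intensities)
}

#' @rdname event_table
#' @export
channel_names <- function(table) {
  stopifnot(inherits(table, "event_table"))
  colnames(table$intensities)
}

#' Extract one channel's intensities
#'
#' @param table An `event_table`.
#' @param channel Channel name.
#' @return Numeric vector of linear-scale intensities, one per event.
#' @export
channel_values <- function(table, channel) {
  stopifnot(inherits(table, "event_table"))
  if (!channel %in% channel_names(table)) {
    stop(sprintf("channel '%s' not present in table (channels: %s)",
                 channel, paste(channel_names(table), collapse = ", ")),
         call. = FALSE)
  }
  unname(table$intensities[, channel])
}

#' @rdname event_table
#' @param x An `event_table`.
#' @param i Integer (or logical) row index of events to keep.
#' @param ... Ignored.
#' @export
`[.event_table` <- function(x, i, ...) {
  event_table(
    intensities = x$intensities[i, , drop = FALSE],
    labels = if (is.null(x$labels)) NULL else as.character(x$labels[i]),
    timepoint = x$timepoint,
    event_id = x$event_id[i],
    metadata = x$metadata)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events x %d channels\n",
              n_events(x), length(channel_names(x))))
  cat("  channels:", paste(channel_names(x), collapse = ", "), "\n")
  if (!is.null(x$timepoint)) cat("  timepoint: stage-6 day", x$timepoint, "\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    tab <- tab[tab > 0]
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  gates <- x$metadata$gates
  if (!is.null(gates)) cat("  gates applied:", paste(gates, collapse = " -> "), "\n")
  invisible(x)
}
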