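#' Read and write event tables
#'
#' The canonical interchange format is CSV with header
#' `event_id,label,timepoint,<channel...>`: comma-separated, UTF-8, one row
#' per event, intensities on the linear scale, `label` left empty when
#' ground truth is withheld. Writing is deterministic — fixed row order and
#' floats at 9 significant digits — so identical tables produce
#' byte-identical files; round-trips are lossless at that precision. FCS
#' 3.0/3.1 list-mode files (see [read_fcs()]) can be read for convenience
#' but are never written.
#'
#' @param path File path.
#' @param format `"csv"` (default) or `"fcs"`.
#' @return [read_events()] returns an [event_table()]; [write_events()]
#'   returns `path` invisibly.
#' @examples
#' tab <- simulate_events(default_sc_islet_config(), 50, timepoint = 7)
#' f <- tempfile(fileext = ".csv")
#' write_events(tab, f)
#' tab2 <- read_events(f)
#' n_events(tab2)
#' @export
read_events <- function(path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "fcs") return(read_fcs(path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  need <- c("event_id", "label", "timepoint")
  if (length(names(df)) < 4L || !identical(names(df)[1:3], need)) {
    stop(sprintf(
      "malformed header in %s: expected 'event_id,label,timepoint,<channel...>', got '%s'",
      path, paste(names(df), collapse = ",")), call. = FALSE)
  }
  channels <- names(df)[-(1:3)]
  n <- nrow(df)
  m <- matrix(NA_real_, nrow = n, ncol = length(channels),
              dimnames = list(NULL, channels))
  for (ch in channels) {
    v <- suppressWarnings(as.numeric(df[[ch]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf(
        "non-positive or unparseable intensity '%s' at data row %d, channel '%s'",
        df[[ch]][bad[1L]], bad[1L], ch), call. = FALSE)
    }
    m[, ch] <- v
  }
  labels <- df$label
  labels <- if (n == 0L || all(labels == "")) NULL else {
    if (any(labels == "")) {
      stop("label column must be fully populated or fully empty",
           call. = FALSE)
    }
    labels
  }
  tp <- unique(df$timepoint[df$timepoint != ""])
  timepoint <- if (length(tp) == 1L) as.integer(tp) else NULL
  event_table(m, labels = labels, timepoint = timepoint,
              event_id = if (n > 0L) as.integer(df$event_id) else NULL,
              metadata = list(source = path))
}

#' @rdname read_events
#' @param table An [event_table()].
#' @export
write_events <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  channels <- channel_names(table)
  header <- paste(c("event_id", "label", "timepoint", channels),
                  collapse = ",")
  n <- n_events(table)
  lines <- header
  if (n > 0L) {
    labels <- if (is.null(table$labels)) rep("", n)
              else as.character(table$labels)
    tp <- if (is.null(table$timepoint)) "" else as.character(table$timepoint)
    vals <- apply(table$intensities, 1, function(row) {
      paste(sprintf("%.9g", row), collapse = ",")
    })
    lines <- c(header, paste(table$event_id, labels, tp, vals, sep = ","))
  }
  con <- file(path, open = "wb")  # binary: fixed \n endings on any platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
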