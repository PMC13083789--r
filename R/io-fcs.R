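#' Read an FCS 3.0/3.1 list-mode file
#'
#' Minimal reader for the subset of the FCS standard the pipeline needs:
#' FCS 3.0 or 3.1, list-mode (`$MODE L`), uncompressed floating-point
#' (`$DATATYPE F` or `D`) or fixed-width integer (`$DATATYPE I`, byte-width
#' multiples of 8 bits, no bit masks) data, little- or big-endian byte
#' order. Channel names are taken from the `$PnS` keyword when present,
#' falling back to `$PnN`. Ground-truth labels are never present in FCS
#' data, so the returned table is unlabeled.
#'
#' @param path Path to an FCS file.
#' @return An unlabeled [event_table()] whose metadata records the keyword
#'   text segment.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  con <- file(path, open = "rb")
  on.exit(close(con))

  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop(sprintf("unsupported FCS version '%s' (only FCS3.0/FCS3.1)",
                 trimws(version)), call. = FALSE)
  }
  offs <- as.numeric(trimws(substring(header,
                                      seq(11, 51, by = 8),
                                      seq(18, 58, by = 8))))
  text_start <- offs[1]; text_end <- offs[2]
  data_start <- offs[3]; data_end <- offs[4]

  seek(con, text_start)
  text <- rawToChar(readBin(con, "raw", text_end - text_start + 1))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), by = 2)],
                 toupper(trimws(parts[seq(1, length(parts), by = 2)])))

  need_kw <- function(name) {
    if (!name %in% names(kw)) {
      stop(sprintf("FCS file missing required keyword %s", name),
           call. = FALSE)
    }
    kw[[name]]
  }
  if (toupper(need_kw("$MODE")) != "L") {
    stop(sprintf("unsupported $MODE '%s' (only list mode)", kw[["$MODE"]]),
         call. = FALSE)
  }
  datatype <- toupper(need_kw("$DATATYPE"))
  if (!datatype %in% c("F", "D", "I")) {
    stop(sprintf("unsupported $DATATYPE '%s' (only F, D, I)", datatype),
         call. = FALSE)
  }
  byteord <- need_kw("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop(sprintf("unsupported $BYTEORD '%s'", byteord),
                      call. = FALSE)
  n_par <- as.integer(need_kw("$PAR"))
  n_tot <- as.integer(need_kw("$TOT"))

  # data offsets may live in the TEXT segment when they overflow the header
  if (data_start == 0 && "$BEGINDATA" %in% names(kw)) {
    data_start <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }

  bits <- vapply(seq_len(n_par), function(i) {
    as.integer(need_kw(sprintf("$P%dB", i)))
  }, integer(1))
  chans <- vapply(seq_len(n_par), function(i) {
    key <- sprintf("$P%dS", i)
    s <- if (key %in% names(kw)) kw[[key]] else ""
    if (nzchar(trimws(s))) trimws(s)
    else trimws(need_kw(sprintf("$P%dN", i)))
  }, character(1))

  seek(con, data_start)
  if (datatype %in% c("F", "D")) {
    size <- if (datatype == "F") 4L else 8L
    if (any(bits != size * 8L)) {
      stop(sprintf("$PnB must be %d for $DATATYPE %s", size * 8L, datatype),
           call. = FALSE)
    }
    vals <- readBin(con, "double", n = n_par * n_tot, size = size,
                    endian = endian)
  } else {
    if (any(bits %% 8L != 0L) || any(!bits %in% c(8L, 16L, 32L))) {
      stop("unsupported integer $PnB (only 8/16/32-bit)", call. = FALSE)
    }
    if (length(unique(bits)) != 1L) {
      stop("mixed integer widths across parameters are not supported",
           call. = FALSE)
    }
    vals <- readBin(con, "integer", n = n_par * n_tot, size = bits[1] / 8L,
                    endian = endian, signed = bits[1] > 16L)
    if (bits[1] <= 16L) vals <- as.numeric(vals)  # readBin unsigned<=16
  }
  if (length(vals) < n_par * n_tot) {
    stop("FCS data segment shorter than $TOT x $PAR events", call. = FALSE)
  }
  m <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE,
              dimnames = list(NULL, chans))
  # cytometers can emit zero/negative baseline values; the pipeline's
  # tables are strictly positive, so clamp at a small positive floor
  m[m <= 0] <- 1e-6
  event_table(m, metadata = list(source = path, fcs_version = version,
                                 fcs_keywords = as.list(kw)))
}
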