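# Write a minimal synthetic FCS 3.1 list-mode file for reader tests.
# Layout: 58-byte header, TEXT segment, float32 DATA segment.
write_synthetic_fcs <- function(path, m, datatype = "F",
                                endian = "little",
                                short_names = colnames(m),
                                stain_names = NULL) {
  n_par <- ncol(m)
  n_tot <- nrow(m)
  size <- if (datatype == "D") 8L else 4L
  bits <- if (datatype == "I") 16L else size * 8L

  kv <- c("$MODE", "L", "$DATATYPE", datatype,
          "$BYTEORD", if (endian == "little") "1,2,3,4" else "4,3,2,1",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
  for (i in seq_len(n_par)) {
    kv <- c(kv, sprintf("$P%dN", i), short_names[i],
            sprintf("$P%dB", i),
            as.character(if (datatype == "I") bits else size * 8L),
            sprintf("$P%dR", i), "262144",
            sprintf("$P%dE", i), "0,0")
    if (!is.null(stain_names)) {
      kv <- c(kv, sprintf("$P%dS", i), stain_names[i])
    }
  }
  text <- paste0("/", paste(kv, collapse = "/"), "/")
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  n_bytes <- n_par * n_tot * (if (datatype == "I") bits / 8L else size)
  data_end <- data_start + n_bytes - 1L

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  stopifnot(nchar(header) == 58L)

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  flat <- as.vector(t(m))  # row-major: event by event
  if (datatype == "I") {
    writeBin(as.integer(flat), con, size = 2L, endian = endian)
  } else {
    writeBin(as.double(flat), con, size = size, endian = endian)
  }
  invisible(path)
}
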