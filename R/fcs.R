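# Minimal FCS 3.0/3.1 list-mode reader/writer: header offsets, TEXT
# keyword segment, uncompressed DATA segment in float, double or integer
# type, both byte orders. Channel names resolve by $PnS (stain) falling
# back to $PnN (short name). Covers the interchange need of this package;
# gating, spillover and analysis segments are out of scope.

.fcs_byte_order <- function(kw) {
  bo <- kw[["$BYTEORD"]]
  if (is.null(bo) || bo %in% c("1,2,3,4", "1,2")) "little"
  else if (bo %in% c("4,3,2,1", "2,1")) "big"
  else stop("unsupported $BYTEORD: ", bo, call. = FALSE)
}

#' Read an FCS file
#'
#' Parses FCS 3.0/3.1 list-mode data: `$DATATYPE` F (float), D (double) or
#' I (16/32-bit integer), either byte order. Returns the raw event matrix;
#' no transform or compensation is applied.
#'
#' @param path FCS file path.
#' @return List with `values` (events x parameters matrix, columns named by
#'   `$PnS` falling back to `$PnN`) and `keywords` (named character list).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version, call. = FALSE)
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(header, a, b))))
  text_begin <- off(11, 18); text_end <- off(19, 26)
  data_begin <- off(27, 34); data_end <- off(35, 42)
  seek(con, text_begin)
  txt <- rawToChar(readBin(con, "raw", text_end - text_begin + 1L))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  parts <- parts[seq_len(length(parts) %/% 2 * 2)]
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(as.list(vals), keys)
  if (!is.na(data_begin) && data_begin == 0) {
    data_begin <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])
  type <- kw[["$DATATYPE"]]
  endian <- .fcs_byte_order(kw)
  seek(con, data_begin)
  nval <- p * n
  values <- switch(type,
    F = readBin(con, "numeric", nval, size = 4L, endian = endian),
    D = readBin(con, "numeric", nval, size = 8L, endian = endian),
    I = {
      bits <- as.integer(kw[["$P1B"]])
      if (!bits %in% c(16L, 32L))
        stop("only 16- or 32-bit integer data supported", call. = FALSE)
      readBin(con, "integer", nval, size = bits %/% 8L,
              signed = bits > 16L, endian = endian)
    },
    stop("unsupported $DATATYPE: ", type, call. = FALSE))
  M <- matrix(as.numeric(values), nrow = n, ncol = p, byrow = TRUE)
  nm <- vapply(seq_len(p), function(i) {
    s <- kw[[sprintf("$P%dS", i)]]
    if (!is.null(s) && nzchar(s)) s else kw[[sprintf("$P%dN", i)]]
  }, "")
  colnames(M) <- nm
  list(values = M, keywords = kw)
}

#' Write an FCS 3.0 file
#'
#' Emits single-precision float list-mode data, little endian, with the
#' matrix column names as both `$PnN` and `$PnS`. Primarily an
#' interchange/testing writer; keyword coverage is the required minimum.
#'
#' @param values numeric events x parameters matrix with column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(values, path) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("values must have column names", call. = FALSE)
  n <- nrow(values); p <- ncol(values)
  d <- "/"
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p))
  for (i in seq_len(p)) {
    rng <- max(1, ceiling(max(abs(values[, i]))))
    kv <- c(kv, sprintf("$P%dN", i), colnames(values)[i],
            sprintf("$P%dS", i), colnames(values)[i],
            sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), as.character(rng))
  }
  if (any(grepl(d, kv, fixed = TRUE)))
    stop("keyword values may not contain the delimiter '", d, "'", call. = FALSE)
  text_of <- function(bd, ed) {
    txt <- paste0(d, paste(kv, collapse = d), d)
    txt <- sub("%BD%", sprintf("%010d", bd), txt, fixed = TRUE)
    sub("%ED%", sprintf("%010d", ed), txt, fixed = TRUE)
  }
  text_begin <- 58L
  text_len <- nchar(text_of(0L, 0L))
  text_end <- text_begin + text_len - 1L
  data_begin <- text_begin + text_len
  data_end <- data_begin + 4L * n * p - 1L
  txt <- text_of(data_begin, data_end)
  hdr <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                 text_begin, text_end,
                 if (data_end <= 99999999) data_begin else 0L,
                 if (data_end <= 99999999) data_end else 0L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}
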