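#' Read a flow cytometry standard (FCS) list-mode file
#'
#' Minimal reader for FCS 3.0/3.1 list-mode files as produced by common
#' acquisition software and by [write_fcs()]. The event matrix is returned
#' exactly as stored, in acquisition order, with no compensation, spillover
#' correction or transformation of any kind.
#'
#' Supported data types are `$DATATYPE` `F` (32-bit float), `D` (64-bit
#' float) and `I` (16- or 32-bit unsigned integers, uniform width across
#' parameters). Both byte orders are handled.
#'
#' @param path Path to an FCS file.
#' @param markers Optional character vector of parameter (`$PnN`) names to
#'   keep. Columns are returned in the order of `markers`. Unknown names
#'   raise an error listing the available parameters.
#' @return Numeric matrix of size events x parameters with parameter names
#'   as column names.
#' @seealso [write_fcs()], [assemble_dataset()]
#' @export
read_fcs <- function(path, markers = NULL) {
  if (!file.exists(path)) {
    stop("FCS file not found: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header, type = "bytes") < 58L) {
    stop("corrupt FCS file (truncated header): ", path)
  }
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version '", version, "' in ", path,
         " (FCS 3.0/3.1 supported)")
  }
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(header, a, b))))
  text_start <- off(11L, 18L)
  text_end   <- off(19L, 26L)
  data_start <- off(27L, 34L)
  data_end   <- off(35L, 42L)
  if (is.na(text_start) || is.na(text_end) || text_end <= text_start) {
    stop("corrupt FCS file (bad TEXT segment offsets): ", path)
  }

  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) < 2L) stop("corrupt FCS file (empty TEXT segment): ", path)
  if (length(parts) %% 2L == 1L) parts <- c(parts, "")
  keys <- toupper(trimws(parts[seq(1L, length(parts), by = 2L)]))
  vals <- trimws(parts[seq(2L, length(parts), by = 2L)])
  kw <- stats::setNames(vals, keys)
  get_kw <- function(key, required = TRUE) {
    if (key %in% names(kw)) return(kw[[key]])
    if (required) stop("FCS file missing required keyword ", key, ": ", path)
    NULL
  }

  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))
  datatype <- toupper(get_kw("$DATATYPE"))
  mode <- toupper(get_kw("$MODE"))
  if (!identical(mode, "L")) stop("only list-mode ($MODE L) FCS supported: ", path)
  byteord <- get_kw("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  # header offsets may be 0 for large files; fall back to TEXT keywords
  if (is.na(data_start) || data_start == 0) data_start <- as.numeric(get_kw("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0) data_end <- as.numeric(get_kw("$ENDDATA"))

  pnn <- character(n_par)
  bits <- integer(n_par)
  for (j in seq_len(n_par)) {
    nm <- get_kw(paste0("$P", j, "N"), required = FALSE)
    pnn[j] <- if (is.null(nm) || !nzchar(nm)) paste0("P", j) else nm
    bj <- get_kw(paste0("$P", j, "B"), required = FALSE)
    bits[j] <- if (is.null(bj)) NA_integer_ else as.integer(bj)
  }

  n_values <- n_par * n_tot
  seek(con, data_start)
  if (datatype == "F") {
    raw_vals <- readBin(con, "numeric", n = n_values, size = 4L, endian = endian)
  } else if (datatype == "D") {
    raw_vals <- readBin(con, "numeric", n = n_values, size = 8L, endian = endian)
  } else if (datatype == "I") {
    width <- unique(bits[!is.na(bits)])
    if (length(width) != 1L || !width %in% c(16L, 32L)) {
      stop("integer FCS data requires a uniform $PnB of 16 or 32: ", path)
    }
    if (width == 16L) {
      raw_vals <- readBin(con, "integer", n = n_values, size = 2L,
                          signed = FALSE, endian = endian)
    } else {
      raw_vals <- readBin(con, "integer", n = n_values, size = 4L, endian = endian)
      raw_vals[raw_vals < 0] <- raw_vals[raw_vals < 0] + 2^32
    }
    raw_vals <- as.numeric(raw_vals)
  } else {
    stop("unsupported $DATATYPE '", datatype, "': ", path)
  }
  if (length(raw_vals) < n_values) {
    stop("corrupt FCS file (DATA segment shorter than $TOT x $PAR): ", path)
  }

  x <- matrix(raw_vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(x) <- pnn
  if (!is.null(markers)) {
    x <- select_markers(x, markers, context = path)
  }
  x
}

# column subset by marker name with an informative error
select_markers <- function(x, markers, context = "matrix") {
  idx <- match(markers, colnames(x))
  if (anyNA(idx)) {
    stop("marker(s) not found in ", context, ": ",
         paste(markers[is.na(idx)], collapse = ", "),
         "; available: ", paste(colnames(x), collapse = ", "))
  }
  x[, idx, drop = FALSE]
}

#' Write a cell matrix as an FCS 3.1 list-mode file
#'
#' Writes events as 32-bit little-endian floats (`$DATATYPE F`, `$MODE L`).
#' Used to produce synthetic fixtures that round-trip through [read_fcs()].
#'
#' @param values Numeric matrix, cells x markers.
#' @param path Output file path.
#' @param marker_names Parameter names (`$PnN`); defaults to the column
#'   names of `values`.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(values, path, marker_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  J <- ncol(values)
  if (n < 1L || J < 1L) stop("cannot write an empty FCS file")
  if (is.null(marker_names)) marker_names <- paste0("P", seq_len(J))
  if (length(marker_names) != J) stop("marker_names must have one name per column")
  if (any(!is.finite(values))) stop("FCS values must be finite")

  delim <- "/"
  build_text <- function(begin_data, end_data) {
    kw <- c(
      "$DATATYPE" = "F",
      "$MODE" = "L",
      "$BYTEORD" = "1,2,3,4",
      "$PAR" = as.character(J),
      "$TOT" = as.character(n),
      "$NEXTDATA" = "0",
      "$BEGINANALYSIS" = "0",
      "$ENDANALYSIS" = "0",
      "$BEGINSTEXT" = "0",
      "$ENDSTEXT" = "0",
      "$BEGINDATA" = sprintf("%010d", begin_data),
      "$ENDDATA" = sprintf("%010d", end_data)
    )
    for (j in seq_len(J)) {
      kw[paste0("$P", j, "N")] <- marker_names[j]
      kw[paste0("$P", j, "B")] <- "32"
      kw[paste0("$P", j, "E")] <- "0,0"
      kw[paste0("$P", j, "R")] <- "262144"
    }
    paste0(delim, paste0(names(kw), delim, unname(kw), delim, collapse = ""))
  }

  text_start <- 58L
  # fixed-width data offsets make the TEXT length independent of their value
  text <- build_text(0L, 0L)
  text_end <- text_start + nchar(text, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * J - 1L
  text <- build_text(data_start, data_end)

  hdr_off <- function(v) {
    if (v > 99999999) "       0" else formatC(v, width = 8L)
  }
  header <- paste0("FCS3.1    ",
                   hdr_off(text_start), hdr_off(text_end),
                   hdr_off(data_start), hdr_off(data_end),
                   hdr_off(0L), hdr_off(0L))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, text), con, eos = NULL, useBytes = TRUE)
  writeBin(as.vector(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}
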