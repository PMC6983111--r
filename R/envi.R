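#' Read an ENVI hypercube (header + binary pair)
#'
#' Parses the ASCII `.hdr` and reads the companion flat-binary cube.
#' Supported interleaves: BSQ (band-sequential), BIL (band-interleaved-
#' by-line), BIP (band-interleaved-by-pixel); data types 4 (float32) and
#' 5 (float64); little- or big-endian byte order. The header's
#' `wavelength` block supplies the band axis.
#'
#' @param path path to the `.hdr` file, or to the binary file if a
#'   sibling `.hdr` exists.
#' @return a [hyper_cube]; `meta$source` records the file, `meta` also
#'   carries any `calibrated` flag saved by [write_envi()].
#' @seealso [write_envi()]
#' @export
read_envi <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path)
  bin_path <- sub("\\.hdr$", "", hdr_path)
  if (!file.exists(bin_path)) {
    # header may be named cube.dat.hdr or cube.hdr next to cube.dat
    alt <- list.files(dirname(hdr_path),
                      pattern = paste0("^", gsub("([.\\\\+*?\\[^\\]$(){}=!<>|:-])",
                                                 "\\\\\\1",
                                                 basename(bin_path)), "\\."),
                      full.names = TRUE)
    alt <- setdiff(alt, hdr_path)
    if (length(alt) == 1L) bin_path <- alt
    else stop("ENVI binary companion of ", hdr_path, " not found")
  }

  h <- parse_envi_header(hdr_path)
  for (fld in c("samples", "lines", "bands", "data type", "interleave")) {
    if (is.null(h[[fld]]))
      stop("ENVI header missing required field: '", fld, "'")
  }
  if (is.null(h[["wavelength"]]))
    stop("ENVI header has no 'wavelength' list; supply a band axis ",
         "(re-write the file with write_envi() giving wavelengths)")

  samples <- as.integer(h[["samples"]])   # columns
  lines   <- as.integer(h[["lines"]])    # rows
  bands   <- as.integer(h[["bands"]])
  dtype   <- as.integer(h[["data type"]])
  offset  <- if (is.null(h[["header offset"]])) 0L else as.integer(h[["header offset"]])
  interleave <- tolower(h[["interleave"]])
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported ENVI interleave: '", interleave, "'")
  wl <- as.numeric(strsplit(h[["wavelength"]], ",")[[1]])
  if (length(wl) != bands)
    stop(sprintf("ENVI header field 'wavelength' has %d entries, 'bands' says %d",
                 length(wl), bands))

  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype,
                      " (supported: 4 = float32, 5 = float64)"))
  n <- samples * lines * bands
  expected <- offset + as.numeric(n) * size
  actual <- file.info(bin_path)$size
  if (!isTRUE(all.equal(expected, actual)))
    stop(sprintf(
      "ENVI binary %s is %d bytes but header fields imply %d (samples=%d, lines=%d, bands=%d, data type=%d)",
      bin_path, actual, as.integer(expected), samples, lines, bands, dtype))

  endian <- if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) == 1L)
    "big" else "little"
  con <- file(bin_path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", n = offset)
  v <- readBin(con, "numeric", n = n, size = size, endian = endian)

  # fastest-varying order per interleave; aperm back to (row, col, band)
  values <- switch(interleave,
    bsq = aperm(array(v, dim = c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(bands, samples, lines)), c(3, 2, 1)))

  meta <- list(source = normalizePath(bin_path), interleave = interleave)
  if (!is.null(h[["description"]])) {
    saved <- parse_envi_meta(h[["description"]])
    meta <- utils::modifyList(saved, meta)
  }
  hyper_cube(values, wl, meta)
}

#' Write a hypercube as an ENVI header + binary pair
#'
#' Values are stored as float64 so [read_envi()] round-trips
#' bit-for-bit. The `meta` entries that are length-1 atomic (notably
#' `calibrated`) are serialized into the header description and restored
#' on read.
#'
#' @param cube a [hyper_cube].
#' @param path output path for the binary cube; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  # revalidate: constructor invariants must hold before anything is written
  cube <- hyper_cube(cube$values, cube$wavelengths, cube$meta)
  d <- dim(cube$values)
  hdr_path <- paste0(path, ".hdr")

  v <- switch(interleave,
    bsq = as.vector(aperm(cube$values, c(2, 1, 3))),
    bil = as.vector(aperm(cube$values, c(2, 3, 1))),
    bip = as.vector(aperm(cube$values, c(3, 2, 1))))

  hdr <- c(
    "ENVI",
    paste0("description = {", format_envi_meta(cube$meta), "}"),
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    paste0("interleave = ", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(format(cube$wavelengths, digits = 12,
                                          trim = TRUE, scientific = FALSE),
                                   collapse = ", "), "}"))
  ok <- tryCatch({
    writeLines(hdr, hdr_path)
    con <- file(path, "wb")
    writeBin(v, con, size = 8L, endian = "little")
    close(con)
    TRUE
  }, error = function(e) stop("cannot write ENVI pair at ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

# --- header helpers ---------------------------------------------------------

parse_envi_header <- function(hdr_path) {
  raw <- readLines(hdr_path, warn = FALSE)
  txt <- paste(raw, collapse = "\n")
  if (!grepl("^\\s*ENVI", txt))
    stop("file does not start with the ENVI magic line: ", hdr_path)
  # join { ... } blocks that span lines, then split "key = value"
  txt <- sub("^\\s*ENVI\\s*\n?", "", txt)
  h <- list()
  pos <- 1L
  chars <- txt
  # simple state machine: split on newlines outside braces
  lines_out <- character()
  depth <- 0L; buf <- ""
  for (ch in strsplit(chars, "")[[1]]) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "\n" && depth == 0L) {
      lines_out <- c(lines_out, buf); buf <- ""
    } else buf <- paste0(buf, ch)
  }
  if (nzchar(buf)) lines_out <- c(lines_out, buf)
  for (ln in lines_out) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub("^\\{|\\}$", "", val)
    val <- gsub("\n", " ", val)
    if (!is.null(h[[key]]))
      stop("contradictory ENVI header: field '", key, "' appears twice")
    h[[key]] <- trimws(val)
  }
  h
}

# meta <-> description string ("key=value; key=value") for scalar entries
format_envi_meta <- function(meta) {
  keep <- vapply(meta, function(x) is.atomic(x) && length(x) == 1L, logical(1))
  if (!any(keep)) return("whitenir cube")
  paste(vapply(names(meta)[keep], function(k)
    paste0(k, "=", as.character(meta[[k]])), character(1)), collapse = "; ")
}

parse_envi_meta <- function(desc) {
  parts <- strsplit(desc, ";")[[1]]
  out <- list()
  for (p in parts) {
    if (!grepl("=", p)) next
    k <- trimws(sub("=.*$", "", p))
    v <- trimws(sub("^[^=]*=", "", p))
    out[[k]] <- utils::type.convert(v, as.is = TRUE)
  }
  out
}
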