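# ENVI cube I/O: plain-text .hdr header plus a headerless binary image file.
# Supported interleaves: bil, bip, bsq. Data is read in whatever stored type
# the header declares (byte/int16/int32/float32/float64/uint16) and promoted
# to double; write_envi always stores float64 so roundtrips are bit-exact.

envi_dtype <- list(`1` = list(what = "integer", size = 1, signed = FALSE),
                   `2` = list(what = "integer", size = 2, signed = TRUE),
                   `3` = list(what = "integer", size = 4, signed = TRUE),
                   `4` = list(what = "numeric", size = 4, signed = TRUE),
                   `5` = list(what = "numeric", size = 8, signed = TRUE),
                   `12` = list(what = "integer", size = 2, signed = FALSE))

# Locate the binary companion of a header file.
envi_binary_path <- function(header_path, must_exist = TRUE) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  for (cand in c(paste0(base, ".dat"), base, paste0(base, ".img"))) {
    if (file.exists(cand) && !dir.exists(cand)) return(cand)
  }
  if (must_exist)
    stop_input("no ENVI binary found next to header ", header_path)
  paste0(base, ".dat")
}

# Parse an ENVI header into a named list; multi-line { ... } values are
# joined before splitting on the first '='.
parse_envi_header <- function(header_path) {
  if (!file.exists(header_path))
    stop_input("ENVI header not found: ", header_path)
  txt <- readLines(header_path, warn = FALSE)
  if (length(txt) == 0 || !grepl("^ENVI", txt[1]))
    stop_input("not an ENVI header (missing ENVI magic line): ", header_path)
  fields <- list()
  buf <- ""
  depth <- 0
  for (line in txt[-1]) {
    buf <- if (nzchar(buf)) paste(buf, line) else line
    depth <- depth + lengths(regmatches(line, gregexpr("\\{", line))) -
      lengths(regmatches(line, gregexpr("\\}", line)))
    if (depth > 0) next
    if (grepl("=", buf, fixed = TRUE)) {
      key <- tolower(trimws(sub("=.*$", "", buf)))
      val <- trimws(sub("^[^=]*=", "", buf))
      fields[[key]] <- val
    }
    buf <- ""
  }
  fields
}

parse_brace_list <- function(x) {
  x <- gsub("[{}]", "", x)
  as.numeric(trimws(strsplit(x, ",")[[1]]))
}

#' Read an ENVI hyperspectral cube
#'
#' @param header_path path to the `.hdr` text header; the binary image is
#'   located next to it (same basename, or `.dat`/`.img` extension).
#' @return A [hypercube()]; unknown header fields are kept in `$meta`.
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path) {
  h <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  missing <- setdiff(need, names(h))
  if (length(missing))
    stop_input("ENVI header missing field(s): ", paste(missing, collapse = ", "))
  S <- as.integer(h$samples); L <- as.integer(h$lines)
  B <- as.integer(h$bands)
  interleave <- tolower(trimws(h$interleave))
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop_input("unsupported interleave: ", interleave)
  if (is.null(h$wavelength))
    stop_input("ENVI header has no wavelength list")
  wl <- parse_brace_list(h$wavelength)
  if (length(wl) != B)
    stop_input("wavelength list length ", length(wl), " != bands ", B)
  if (B > 1 && any(diff(wl) <= 0))
    stop_input("wavelength list is not strictly increasing")
  dt <- envi_dtype[[trimws(h[["data type"]])]]
  if (is.null(dt))
    stop_input("unsupported ENVI data type: ", h[["data type"]])
  endian <- if (!is.null(h[["byte order"]]) &&
                trimws(h[["byte order"]]) == "1") "big" else "little"
  bin <- envi_binary_path(header_path)
  n <- S * L * B
  v <- readBin(bin, what = dt$what, n = n, size = dt$size,
               signed = dt$signed, endian = endian)
  if (length(v) != n)
    stop_input("ENVI binary shorter than header promises (", length(v),
               " of ", n, " values)")
  v <- as.numeric(v)
  data <- switch(interleave,
    bsq = aperm(array(v, c(S, L, B)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(S, B, L)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(B, S, L)), c(3L, 2L, 1L)))
  known <- c(need, "wavelength", "byte order", "header offset", "file type",
             "wavelength units", "description")
  meta <- h[setdiff(names(h), known)]
  hypercube(data, wl, meta)
}

#' Write a hyperspectral cube in ENVI format
#'
#' Writes `<base>.hdr` (text) and `<base>.dat` (little-endian float64
#' binary). Metadata entries with scalar character/numeric values are
#' serialized as extra header lines and survive a roundtrip through
#' [read_envi()].
#'
#' @param cube a [hypercube()].
#' @param header_path output header path (should end in `.hdr`).
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @return Invisibly, the header path.
#' @export
write_envi <- function(cube, header_path, interleave = c("bil", "bip", "bsq")) {
  stopifnot(inherits(cube, "HyperCube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  L <- d[1]; S <- d[2]; B <- d[3]
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2L, 1L, 3L))),
    bil = as.vector(aperm(cube$data, c(2L, 3L, 1L))),
    bip = as.vector(aperm(cube$data, c(3L, 2L, 1L))))
  bin <- envi_binary_path(header_path, must_exist = FALSE)
  ok <- tryCatch({
    con <- file(bin, "wb"); on.exit(close(con), add = TRUE)
    writeBin(as.numeric(v), con, size = 8, endian = "little")
    TRUE
  }, error = function(e) stop_input("cannot write ENVI binary ", bin, ": ",
                                    conditionMessage(e)))
  hdr <- c("ENVI",
           "file type = ENVI Standard",
           paste0("samples = ", S),
           paste0("lines = ", L),
           paste0("bands = ", B),
           "header offset = 0",
           "data type = 5",
           paste0("interleave = ", interleave),
           "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = { ",
                  paste(format(cube$wavelengths_nm, digits = 15,
                               trim = TRUE, scientific = FALSE),
                        collapse = ", "), " }"))
  for (k in names(cube$meta)) {
    val <- cube$meta[[k]]
    if (is.atomic(val) && length(val) == 1L)
      hdr <- c(hdr, paste0(k, " = ", as.character(val)))
  }
  writeLines(hdr, header_path)
  invisible(header_path)
}
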