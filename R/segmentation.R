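#' Otsu threshold of a grayscale image
#'
#' Chooses the cut maximizing between-class variance over a 256-bin
#' histogram of the image's value range. Foreground is defined as values
#' strictly greater than the returned threshold. Ties between equally good
#' cuts break toward the lower threshold.
#'
#' @param gray numeric matrix with at least two distinct values.
#' @param nbins histogram resolution (default 256).
#' @return Scalar threshold (a bin edge within the value range).
#' @export
otsu_threshold <- function(gray, nbins = 256L) {
  v <- as.numeric(gray)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (rng[1] == rng[2])
    stop_input("constant image: no Otsu threshold exists")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nbins)
  counts <- tabulate(bin, nbins)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * mids)
  n <- w0[nbins]; mtot <- m0[nbins]
  t_cand <- seq_len(nbins - 1L)
  n0 <- w0[t_cand]; n1 <- n - n0
  valid <- n0 > 0 & n1 > 0
  sigma_b <- rep(-Inf, nbins - 1L)
  mu0 <- m0[t_cand][valid] / n0[valid]
  mu1 <- (mtot - m0[t_cand][valid]) / n1[valid]
  sigma_b[valid] <- (n0[valid] / n) * (n1[valid] / n) * (mu0 - mu1)^2
  t_best <- which.max(sigma_b)  # ties -> lowest bin
  edges[t_best + 1L]
}

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

disk_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

erode_mask <- function(m, off) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out & shift_mask(m, -off$dr[i], -off$dc[i])
  out
}

dilate_mask <- function(m, off) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(m, off$dr[i], off$dc[i])
  out
}

#' Morphological cleanup of a seed mask
#'
#' Opening (erosion then dilation, removing specks smaller than the
#' structuring element) followed by closing (dilation then erosion, filling
#' holes), both with a disk structuring element.
#'
#' @param mask logical matrix, `TRUE` = seed pixel.
#' @param se_radius disk radius in pixels (>= 1).
#' @return Cleaned logical matrix of the same shape.
#' @export
clean_mask <- function(mask, se_radius = 2L) {
  stopifnot(is.matrix(mask), se_radius >= 1)
  mask <- mask & TRUE  # coerce to logical
  off <- disk_offsets(se_radius)
  opened <- dilate_mask(erode_mask(mask, off), off)
  erode_mask(dilate_mask(opened, off), off)
}

#' Label connected components and number seeds deterministically
#'
#' 8-connected components with area at least `min_area` are numbered
#' `1..K` in raster order (row-major, origin top-left) of each component's
#' first pixel, i.e. its topmost-then-leftmost pixel; smaller components are
#' dropped to background. This makes seed numbering reproducible regardless
#' of discovery order.
#'
#' @param mask logical matrix (ideally from [clean_mask()]).
#' @param min_area minimum component area in pixels.
#' @return Integer matrix; 0 = background, `1..K` = seed ids.
#' @export
label_and_number <- function(mask, min_area = 20L) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (!length(fg)) return(labels)
  # raster (row-major) scan order
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  fg <- fg[order(rows, cols)]
  nb_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  comp_pixels <- list()
  k <- 0L
  for (p in fg) {
    if (labels[p] != 0L) next
    k <- k + 1L
    stack <- p
    labels[p] <- k
    members <- integer(0)
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, q)
      qr <- ((q - 1L) %% nr) + 1L
      qc <- ((q - 1L) %/% nr) + 1L
      rr <- qr + nb_dr; cc <- qc + nb_dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nbr <- (cc[ok] - 1L) * nr + rr[ok]
      nbr <- nbr[mask[nbr] & labels[nbr] == 0L]
      if (length(nbr)) {
        labels[nbr] <- k
        stack <- c(stack, nbr)
      }
    }
    comp_pixels[[k]] <- members
  }
  # area filter + renumber preserving raster order of first pixels
  keep <- which(lengths(comp_pixels) >= min_area)
  out <- matrix(0L, nr, nc)
  for (i in seq_along(keep))
    out[comp_pixels[[keep[i]]]] <- i
  out
}

#' Per-seed mean spectra table
#'
#' Container for the pipeline's central tabular object: one row per seed,
#' the arithmetic mean reflectance of its member pixels at every band.
#'
#' @param spectra numeric matrix, seeds x bands.
#' @param wavelengths_nm shared band grid.
#' @param seed_id unique ascending integer ids.
#' @param class_label optional integer severity labels (0 = healthy ..
#'   4 = heavy mold), or `NULL` when unknown.
#' @return Object of class `SeedSpectraTable`.
#' @export
seed_spectra_table <- function(spectra, wavelengths_nm, seed_id,
                               class_label = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths_nm))
    stop_input("spectra columns must match wavelength grid length")
  if (anyDuplicated(seed_id) || is.unsorted(seed_id))
    stop_input("seed_id must be unique and ascending")
  if (length(seed_id) != nrow(spectra))
    stop_input("one seed_id per spectrum row required")
  if (nrow(spectra) && !all(is.finite(spectra)))
    stop_input("spectra contain non-finite values")
  if (!is.null(class_label) && length(class_label) != nrow(spectra))
    stop_input("class_label length must match row count")
  structure(list(seed_id = as.integer(seed_id),
                 class_label = if (is.null(class_label)) NULL
                               else as.integer(class_label),
                 spectra = spectra,
                 wavelengths_nm = as.numeric(wavelengths_nm)),
            class = "SeedSpectraTable")
}

#' @export
print.SeedSpectraTable <- function(x, ...) {
  cat(sprintf("SeedSpectraTable: %d seeds x %d bands%s\n",
              nrow(x$spectra), ncol(x$spectra),
              if (is.null(x$class_label)) "" else
                paste0(" (", length(unique(x$class_label)), " classes)")))
  invisible(x)
}

#' Extract per-seed mean spectra from a labeled cube
#'
#' For each seed id `k` in `labels`, averages the spectra of all member
#' pixels band by band. Rows are ordered by seed id.
#'
#' @param cube a reflectance [hypercube()].
#' @param labels integer label matrix from [label_and_number()]; spatial
#'   shape must match the cube.
#' @param class_of_seed optional named vector/list mapping seed id to class
#'   label (from the plate layout), or a plain vector of length K.
#' @return A [seed_spectra_table()]; empty (0 rows) when K = 0.
#' @export
extract_spectra <- function(cube, labels, class_of_seed = NULL) {
  stopifnot(inherits(cube, "HyperCube"), is.matrix(labels))
  d <- dim(cube$data)
  if (!identical(dim(labels), d[1:2]))
    stop_input("labels shape ", paste(dim(labels), collapse = "x"),
               " does not match cube spatial shape ",
               paste(d[1:2], collapse = "x"))
  B <- d[3]
  K <- max(labels)
  if (K == 0L)
    return(seed_spectra_table(matrix(numeric(0), 0, B),
                              cube$wavelengths_nm, integer(0)))
  flat <- matrix(cube$data, nrow = d[1] * d[2], ncol = B)
  lab <- as.integer(labels)
  fg <- lab > 0L
  sums <- rowsum(flat[fg, , drop = FALSE], lab[fg])
  counts <- tabulate(lab[fg], K)
  means <- sums / counts
  cls <- NULL
  if (!is.null(class_of_seed)) {
    cls <- if (!is.null(names(class_of_seed)))
      as.integer(unlist(class_of_seed)[as.character(seq_len(K))])
    else as.integer(unlist(class_of_seed))[seq_len(K)]
  }
  seed_spectra_table(means, cube$wavelengths_nm, seq_len(K), cls)
}

#' Write / read a seed-spectra table as CSV
#'
#' Plain-text exchange format: header `seed_id,class,w<nm>,...`; `class` is
#' empty when labels are unknown.
#'
#' @param table a [seed_spectra_table()].
#' @param path CSV path.
#' @return `write_spectra_csv` the path, invisibly; `read_spectra_csv` a
#'   `SeedSpectraTable`.
#' @export
write_spectra_csv <- function(table, path) {
  stopifnot(inherits(table, "SeedSpectraTable"))
  df <- data.frame(seed_id = table$seed_id,
                   class = if (is.null(table$class_label)) NA_integer_
                           else table$class_label)
  sp <- as.data.frame(table$spectra)
  names(sp) <- paste0("w", format(table$wavelengths_nm, trim = TRUE,
                                  digits = 10, scientific = FALSE))
  write.csv(cbind(df, sp), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wcols <- grep("^w[0-9]", names(df))
  wl <- as.numeric(sub("^w", "", names(df)[wcols]))
  cls <- if (all(is.na(df$class))) NULL else as.integer(df$class)
  seed_spectra_table(as.matrix(df[, wcols, drop = FALSE]), wl,
                     as.integer(df$seed_id), cls)
}
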