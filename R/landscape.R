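#' Landcover raster
#'
#' A categorical landcover grid in a projected CRS, NLCD-like (30 m default),
#' condensed to three coarse classes plus an excluded class (developed,
#' cultivated, open water, barren). Values are stored as an integer matrix
#' with row 1 at the *bottom* (y increasing with row index); cell (i, j)
#' covers the half-open square
#' `[x0 + (j-1) s, x0 + j s) x [y0 + (i-1) s, y0 + i s)`.
#'
#' @param values Integer matrix of class codes.
#' @param origin Numeric length-2, coordinates of the lower-left corner.
#' @param cell_size Cell edge, metres.
#' @param legend Named integer vector mapping class names to codes.
#' @return Object of class `landscape_raster`.
#' @export
landscape_raster <- function(values, origin = c(0, 0), cell_size = 30,
                             legend = c(excluded = 0L, bottomland = 1L,
                                        upland_pine = 2L, grassland = 3L)) {
  stopifnot(is.matrix(values), cell_size > 0)
  storage.mode(values) <- "integer"
  if (any(is.na(values))) stop("every cell must be classed", call. = FALSE)
  if (!all(values %in% legend)) {
    stop("raster contains codes absent from the legend", call. = FALSE)
  }
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = cell_size, legend = legend),
            class = "landscape_raster")
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat(sprintf("<landscape_raster> %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  tab <- table(factor(x$values, levels = x$legend,
                      labels = names(x$legend)))
  print(round(tab / sum(tab), 3))
  invisible(x)
}

#' Extent of a landscape raster
#' @param ls A [landscape_raster()].
#' @return `c(xmin, xmax, ymin, ymax)`.
#' @export
raster_extent <- function(ls) {
  c(ls$origin[1], ls$origin[1] + ncol(ls$values) * ls$cell_size,
    ls$origin[2], ls$origin[2] + nrow(ls$values) * ls$cell_size)
}

#' Landcover class at point coordinates
#'
#' Half-open cell convention: a point exactly on a cell's left/bottom edge
#' belongs to that cell.
#'
#' @param ls A [landscape_raster()].
#' @param x,y Numeric vectors of projected coordinates (metres).
#' @return Character vector of class names; `NA` off-raster.
#' @export
class_at <- function(ls, x, y) {
  j <- floor((x - ls$origin[1]) / ls$cell_size) + 1
  i <- floor((y - ls$origin[2]) / ls$cell_size) + 1
  ok <- j >= 1 & j <= ncol(ls$values) & i >= 1 & i <= nrow(ls$values)
  code <- rep(NA_integer_, length(x))
  code[ok] <- ls$values[cbind(i[ok], j[ok])]
  names(ls$legend)[match(code, ls$legend)]
}

#' Write a landscape raster as an ESRI ASCII grid
#'
#' @param ls A [landscape_raster()].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(ls, path) {
  v <- ls$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.6f", ls$origin[1]),
               sprintf("yllcorner %.6f", ls$origin[2]),
               sprintf("cellsize %.6f", ls$cell_size),
               "NODATA_value -9999"), con)
  # ASCII grids are written top row first
  for (i in rev(seq_len(nrow(v)))) {
    writeLines(paste(v[i, ], collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid as a landscape raster
#'
#' @param path `.asc` file path.
#' @param legend Named integer class legend (see [landscape_raster()]).
#' @return A [landscape_raster()].
#' @export
read_esri_ascii <- function(path,
                            legend = c(excluded = 0L, bottomland = 1L,
                                       upland_pine = 2L, grassland = 3L)) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  body <- lines[i:length(lines)]
  rows <- lapply(body[nzchar(trimws(body))], function(l) {
    as.integer(strsplit(trimws(l), "\\s+")[[1]])
  })
  v <- do.call(rbind, rows)
  stopifnot(nrow(v) == hdr$nrows, ncol(v) == hdr$ncols)
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]  # back to bottom-first
  landscape_raster(v, origin = c(hdr$xllcorner, hdr$yllcorner),
                   cell_size = hdr$cellsize, legend = legend)
}

#' Habitat composition of a release-site buffer
#'
#' Buffers the release site by a disc whose area equals the mean resident
#' home-range size (8.3 km^2 by default, i.e. radius ~1.63 km) and tabulates
#' the fraction of raster cells, by class, whose centres fall inside.
#'
#' @param release_xy Numeric length-2, projected metres.
#' @param landcover A [landscape_raster()].
#' @param mean_hr_area_km2 Buffer area in km^2.
#' @return Named numeric vector of class fractions (sums to 1).
#' @export
release_site_composition <- function(release_xy, landcover,
                                     mean_hr_area_km2 = 8.3) {
  r <- sqrt(mean_hr_area_km2 * 1e6 / pi)
  ext <- raster_extent(landcover)
  if (release_xy[1] - r < ext[1] || release_xy[1] + r > ext[2] ||
      release_xy[2] - r < ext[3] || release_xy[2] + r > ext[4]) {
    out_frac <- 1 - disc_coverage_fraction(release_xy, r, ext)
    stop(sprintf(paste0("release-site buffer exits the raster extent ",
                        "(~%.1f%% uncovered)"), 100 * out_frac),
         call. = FALSE)
  }
  s <- landcover$cell_size
  xc <- landcover$origin[1] + (seq_len(ncol(landcover$values)) - 0.5) * s
  yc <- landcover$origin[2] + (seq_len(nrow(landcover$values)) - 0.5) * s
  jj <- which(abs(xc - release_xy[1]) <= r)
  ii <- which(abs(yc - release_xy[2]) <= r)
  sub <- landcover$values[ii, jj, drop = FALSE]
  inside <- outer(yc[ii] - release_xy[2], xc[jj] - release_xy[1],
                  function(dy, dx) dx^2 + dy^2 <= r^2)
  codes <- sub[inside]
  tab <- table(factor(codes, levels = landcover$legend,
                      labels = names(landcover$legend)))
  frac <- as.numeric(tab) / sum(tab)
  names(frac) <- names(tab)
  frac
}

# crude Monte-Carlo-free bound on how much of a disc lies outside an extent
disc_coverage_fraction <- function(centre, r, ext) {
  gx <- seq(centre[1] - r, centre[1] + r, length.out = 101)
  gy <- seq(centre[2] - r, centre[2] + r, length.out = 101)
  inside_disc <- outer(gy - centre[2], gx - centre[1],
                       function(dy, dx) dx^2 + dy^2 <= r^2)
  inside_ext <- outer(gy >= ext[3] & gy <= ext[4],
                      gx >= ext[1] & gx <= ext[2], "&")
  sum(inside_disc & inside_ext) / sum(inside_disc)
}
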