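#' Compute band-ratio predictors from four-band reflectance records
#'
#' Adds the predictor set used by all GAI models to a table of plot-level
#' reflectance records: the three NIR-based simple ratios NIR/Green,
#' NIR/Red, NIR/RE and the NDVI, (NIR - Red)/(NIR + Red). Records with a
#' nonpositive or non-finite band are flagged invalid (column `valid`,
#' reason `"nonpositive reflectance"`) rather than silently dropped;
#' clamping would fabricate ratios.
#'
#' @param records data.frame with at least the band columns `green`, `red`,
#'   `red_edge`, `nir` (fractional reflectance).
#' @return the input with added columns `nir_green`, `nir_red`, `nir_re`,
#'   `ndvi`, `valid` (logical) and `invalid_reason` (NA when valid).
#'   Predictors of invalid records are NA.
#' @export
#' @examples
#' compute_predictors(data.frame(green = 0.05, red = 0.1,
#'                               red_edge = 0.2, nir = 0.5))
compute_predictors <- function(records) {
  miss <- setdiff(.bands, names(records))
  if (length(miss)) {
    stop("missing required band column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bands <- as.matrix(records[, .bands])
  bad <- !is.finite(bands) | bands <= 0
  valid <- !apply(bad, 1, any)
  out <- records
  out$nir_green <- ifelse(valid, records$nir / records$green, NA_real_)
  out$nir_red <- ifelse(valid, records$nir / records$red, NA_real_)
  out$nir_re <- ifelse(valid, records$nir / records$red_edge, NA_real_)
  out$ndvi <- ifelse(valid,
                     (records$nir - records$red) / (records$nir + records$red),
                     NA_real_)
  out$valid <- valid
  out$invalid_reason <- ifelse(valid, NA_character_, "nonpositive reflectance")
  out
}

#' Construct a single-band raster with an affine georeference
#'
#' A minimal raster container for zonal extraction: a numeric matrix (row 1
#' is the top of the image) plus a north-up affine georeference (no
#' rotation) and an optional CRS tag.
#'
#' @param values numeric matrix of reflectance values; row 1 = northernmost
#'   row.
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @param cellsize square pixel edge length in CRS units.
#' @param crs optional CRS identifier string (e.g. "EPSG:25832").
#' @return object of class `band_raster`.
#' @export
band_raster <- function(values, xmin = 0, ymin = 0, cellsize = 1, crs = NA_character_) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), cellsize > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, crs = crs),
            class = "band_raster")
}

# Pixel-center coordinates of a band_raster, row-major.
.pixel_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  x <- r$xmin + (seq_len(nc) - 0.5) * r$cellsize
  y <- r$ymin + (nr - seq_len(nr) + 0.5) * r$cellsize
  list(x = rep(x, each = nr), y = rep(y, times = nc),
       value = as.vector(r$values))
}

#' Read a single-band raster from a TIFF plus ESRI world file
#'
#' Reads the pixel grid with the `tiff` package and the affine georeference
#' from the plain-text six-line world file (`.tfw`). Only north-up,
#' square-pixel affines are supported; rotation terms must be zero.
#'
#' @param path path to a single-band TIFF file.
#' @param world_file path to the world file; defaults to `path` with a
#'   `.tfw` extension.
#' @param crs optional CRS identifier to attach.
#' @return a [band_raster()].
#' @export
read_band_raster <- function(path, world_file = sub("\\.tif{1,2}$", ".tfw", path),
                             crs = NA_character_) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF rasters requires the 'tiff' package", call. = FALSE)
  }
  vals <- tiff::readTIFF(path)  # fractional reflectance; floats read natively
  if (length(dim(vals)) == 3) {
    stop("expected a single-band TIFF; got ", dim(vals)[3], " channels",
         call. = FALSE)
  }
  # world file lines: A (x pixel size), D, B (rotations), E (negative y
  # pixel size), C, F (x/y of the CENTER of the top-left pixel)
  w <- as.numeric(readLines(world_file, n = 6))
  if (length(w) != 6 || any(!is.finite(w))) {
    stop("malformed world file: ", world_file, call. = FALSE)
  }
  if (w[2] != 0 || w[3] != 0 || w[1] <= 0 || w[4] >= 0 || w[1] != -w[4]) {
    stop("only north-up square-pixel world files are supported", call. = FALSE)
  }
  cellsize <- w[1]
  xmin <- w[5] - cellsize / 2
  ymin <- (w[6] + cellsize / 2) - nrow(vals) * cellsize
  band_raster(vals, xmin = xmin, ymin = ymin, cellsize = cellsize, crs = crs)
}

#' Read plot polygons from a GeoJSON file
#'
#' Parses a GeoJSON FeatureCollection of Polygon features, each carrying a
#' `plot_id` property. Only the outer ring of each polygon is used.
#'
#' @param path path to a GeoJSON file.
#' @return list of `plot_polygon` objects (fields `plot_id`, `x`, `y`,
#'   `crs`).
#' @export
read_plot_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  crs <- NA_character_
  if (!is.null(gj$crs$properties$name)) crs <- gj$crs$properties$name
  lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon features are supported; got ", f$geometry$type,
           call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    plot_polygon(xy[, 1], xy[, 2], plot_id = f$properties$plot_id, crs = crs)
  })
}

#' Construct a plot polygon
#'
#' @param x,y vertex coordinates of the outer ring (closed or open).
#' @param plot_id plot identifier.
#' @param crs optional CRS identifier string.
#' @return object of class `plot_polygon`.
#' @export
plot_polygon <- function(x, y, plot_id = NA_character_, crs = NA_character_) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(plot_id = plot_id, x = as.numeric(x), y = as.numeric(y),
                 crs = crs),
            class = "plot_polygon")
}

#' Zonal median reflectance of plot polygons
#'
#' Summarizes all raster pixels whose centers fall inside a plot polygon by
#' their median, the aggregation used for plot-level reflectance
#' extraction. An even pixel count yields the mean of the two central
#' values; pixels on the polygon boundary count as inside.
#'
#' @param rasters a single [band_raster()] or a named list of them (one per
#'   band).
#' @param polygon a [plot_polygon()].
#' @return named numeric vector of per-band medians with attribute
#'   `n_pixels` (per band).
#' @export
zonal_median <- function(rasters, polygon) {
  stopifnot(inherits(polygon, "plot_polygon"))
  if (inherits(rasters, "band_raster")) rasters <- list(value = rasters)
  out <- numeric(0); npx <- integer(0)
  for (nm in names(rasters)) {
    r <- rasters[[nm]]
    stopifnot(inherits(r, "band_raster"))
    if (!is.na(r$crs) && !is.na(polygon$crs) && r$crs != polygon$crs) {
      stop("CRS mismatch: raster '", r$crs, "' vs polygon '", polygon$crs,
           "'", call. = FALSE)
    }
    px <- .pixel_centers(r)
    inside <- pracma::inpolygon(px$x, px$y, polygon$x, polygon$y,
                                boundary = TRUE)
    if (!any(inside)) {
      stop("empty zone: polygon '", polygon$plot_id,
           "' contains no pixel centers of band '", nm, "'", call. = FALSE)
    }
    out[nm] <- median(px$value[inside])
    npx[nm] <- sum(inside)
  }
  attr(out, "n_pixels") <- npx
  out
}
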