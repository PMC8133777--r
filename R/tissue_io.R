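#' Epithelium container: cells, bonds, triangles, lineage
#'
#' The common substrate of all morphometry in this package, patterned after
#' relational (TissueMiner-style) segmentation exports. All geometry is in
#' micrometres; the origin is at the intersection of the averaged AP and DV
#' boundary axes, with x along the DV boundary and y along the AP axis.
#'
#' @param cells data.frame with columns `frame` (integer), `cell_id`
#'   (integer), `track_id` (integer), `x`, `y` (centroid, um), `area` (um^2,
#'   > 0), `region` (character; one of "blade", "AP_boundary", "DV_boundary",
#'   "DV_band", "excluded").
#' @param bonds data.frame with columns `frame`, `cell_a`, `cell_b`; the
#'   neighbor relation. Stored canonically with `cell_a < cell_b`.
#' @param triangles data.frame with columns `frame`, `tri_id`, `cell_a`,
#'   `cell_b`, `cell_c`: the triangulation connecting centroids of
#'   neighboring cells.
#' @param lineage optional data.frame with columns `parent`, `child`,
#'   `frame` (frame at which the child first exists). Cells absent from it
#'   are their own ancestors.
#' @param events optional data.frame event log (`frame`, `type`, `cell_1` ..
#'   `cell_4`, `axis`) as written by [generate_timelapse()].
#' @param meta named list of provenance (seed, generator spec, ...).
#' @return an object of class `"epithelium"`.
#' @export
epithelium <- function(cells, bonds, triangles, lineage = NULL,
                       events = NULL, meta = list()) {
  obj <- structure(
    list(cells = as.data.frame(cells), bonds = canonical_bonds(bonds),
         triangles = as.data.frame(triangles), lineage = lineage,
         events = events, meta = meta),
    class = "epithelium")
  validate_epithelium(obj)
  obj
}

canonical_bonds <- function(bonds) {
  bonds <- as.data.frame(bonds)
  a <- pmin(bonds$cell_a, bonds$cell_b)
  b <- pmax(bonds$cell_a, bonds$cell_b)
  out <- unique(data.frame(frame = bonds$frame, cell_a = a, cell_b = b))
  rownames(out) <- NULL
  out
}

validate_epithelium <- function(x) {
  cl <- x$cells
  need <- c("frame", "cell_id", "track_id", "x", "y", "area", "region")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(cl$area)) || any(cl$area <= 0))
    stop("cell areas must be finite and > 0", call. = FALSE)
  key <- paste(cl$frame, cl$cell_id)
  if (anyDuplicated(key))
    stop("duplicate (frame, cell_id) in cell table", call. = FALSE)
  tr <- x$triangles
  tkey <- paste(tr$frame, tr$cell_a, tr$cell_b, tr$cell_c)
  if (anyDuplicated(tkey))
    stop("duplicate triangles", call. = FALSE)
  # every triangle cell must exist in its frame
  allc <- c(paste(tr$frame, tr$cell_a), paste(tr$frame, tr$cell_b),
            paste(tr$frame, tr$cell_c))
  bad <- !(allc %in% key)
  if (any(bad))
    stop("triangle refers to cell(s) absent from its frame", call. = FALSE)
  invisible(x)
}

#' @export
print.epithelium <- function(x, ...) {
  nf <- length(unique(x$cells$frame))
  cat(sprintf("<epithelium> %d frame(s), %d cell records, %d triangles\n",
              nf, nrow(x$cells), nrow(x$triangles)))
  if (!is.null(x$events))
    cat(sprintf("  events: %d (%s)\n", nrow(x$events),
                paste(names(table(x$events$type)), table(x$events$type),
                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' Frame accessors
#'
#' @param tissue an [epithelium()] object.
#' @param frame frame index.
#' @return `tissue_frames()` returns the sorted frame indices;
#'   `get_frame()` the cells/triangles/bonds of one frame.
#' @export
tissue_frames <- function(tissue) sort(unique(tissue$cells$frame))

#' @rdname tissue_frames
#' @export
get_frame <- function(tissue, frame) {
  list(cells = tissue$cells[tissue$cells$frame == frame, , drop = FALSE],
       bonds = tissue$bonds[tissue$bonds$frame == frame, , drop = FALSE],
       triangles = tissue$triangles[tissue$triangles$frame == frame, ,
                                    drop = FALSE])
}

#' Read segmented-cell tables from disk
#'
#' Reads a directory of CSV tables (`cells.csv`, `bonds.csv`,
#' `triangles.csv`, optionally `lineage.csv`, `events.csv`) into an
#' [epithelium()]. Column names are schema-configurable because relational
#' exports differ between pipelines; positions may be in pixels, in which
#' case `pixel_size` converts them to micrometres.
#'
#' The reader rejects rather than coerces: missing columns are a schema
#' error naming the column, and an asymmetric neighbor relation in
#' `bonds.csv` (a pair listed one way only when the dialect declares
#' directed bonds) is an integrity error listing offending pairs.
#'
#' @param path directory containing the tables.
#' @param schema named list remapping column names, e.g.
#'   `list(cells = c(x = "center_x"))`; defaults assume the package's own
#'   dialect.
#' @param pixel_size um per pixel applied to `x`, `y` (and `area` with
#'   `pixel_size^2`) when given; default `NULL` means tables are already in
#'   um.
#' @param directed_bonds if `TRUE`, `bonds.csv` lists each neighbor pair in
#'   both directions and symmetry is enforced.
#' @return an [epithelium()].
#' @export
read_cell_tables <- function(path, schema = list(), pixel_size = NULL,
                             directed_bonds = FALSE) {
  rd <- function(name, required = TRUE) {
    f <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(f)) {
      if (required) stop("missing table: ", f, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  remap <- function(df, which, need) {
    if (is.null(df)) return(NULL)
    map <- schema[[which]]
    if (!is.null(map))
      for (ours in names(map)) {
        theirs <- map[[ours]]
        if (!theirs %in% names(df))
          stop("schema error in ", which, " table: declared column '",
               theirs, "' (for '", ours, "') not found", call. = FALSE)
        names(df)[names(df) == theirs] <- ours
      }
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("schema error in ", which, " table: missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    df
  }
  cells <- remap(rd("cells"), "cells",
                 c("frame", "cell_id", "track_id", "x", "y", "area", "region"))
  bonds <- remap(rd("bonds"), "bonds", c("frame", "cell_a", "cell_b"))
  tris <- remap(rd("triangles"), "triangles",
                c("frame", "tri_id", "cell_a", "cell_b", "cell_c"))
  lineage <- remap(rd("lineage", required = FALSE), "lineage",
                   c("parent", "child", "frame"))
  events <- rd("events", required = FALSE)
  if (!is.null(pixel_size)) {
    stopifnot(pixel_size > 0)
    cells$x <- cells$x * pixel_size
    cells$y <- cells$y * pixel_size
    cells$area <- cells$area * pixel_size^2
  }
  if (directed_bonds) {
    fwd <- paste(bonds$frame, bonds$cell_a, bonds$cell_b)
    rev <- paste(bonds$frame, bonds$cell_b, bonds$cell_a)
    bad <- !(fwd %in% rev)
    if (any(bad)) {
      off <- utils::head(bonds[bad, , drop = FALSE], 10)
      stop("integrity error: asymmetric neighbor relation for pairs: ",
           paste(sprintf("(%d:%d-%d)", off$frame, off$cell_a, off$cell_b),
                 collapse = ", "), call. = FALSE)
    }
  }
  epithelium(cells, bonds, tris, lineage = lineage, events = events,
             meta = list(source = normalizePath(path, mustWork = FALSE)))
}

#' Write an epithelium to CSV tables
#'
#' Inverse of [read_cell_tables()] in the package's own dialect (CSV with
#' header, UTF-8, '.' decimal, full precision). `read(write(x))` is the
#' identity up to numeric print precision.
#'
#' @param tissue an [epithelium()].
#' @param path output directory (created if needed).
#' @param directed_bonds write bonds in both directions.
#' @return `path`, invisibly.
#' @export
write_cell_tables <- function(tissue, path, directed_bonds = FALSE) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.csv(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     file.path(path, paste0(name, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  bonds <- tissue$bonds
  if (directed_bonds)
    bonds <- rbind(bonds,
                   data.frame(frame = bonds$frame, cell_a = bonds$cell_b,
                              cell_b = bonds$cell_a))
  wr(tissue$cells, "cells")
  wr(bonds, "bonds")
  wr(tissue$triangles, "triangles")
  wr(tissue$lineage, "lineage")
  wr(tissue$events, "events")
  invisible(path)
}

#' Apical height field
#'
#' A 2D raster of apical surface height h(x, y) in um with a pixel-size
#' calibration. Pixel indexing is 0-based with pixel centers at
#' `(i + 0.5) * pixel_size` relative to `origin`.
#'
#' @param values numeric matrix of heights (um); rows index y, columns x.
#' @param pixel_size um per pixel (> 0).
#' @param origin length-2 numeric, um position of the raster corner.
#' @return object of class `"height_field"`.
#' @export
height_field <- function(values, pixel_size, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("height field must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite heights", call. = FALSE)
  stopifnot(length(pixel_size) == 1, pixel_size > 0, length(origin) == 2)
  structure(list(values = values, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("<height_field> %d x %d px @ %.4g um/px, h in [%.3g, %.3g] um\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read / write height-map rasters
#'
#' `read_height_map()` accepts a grayscale TIFF (via the tiff package) or a
#' plain whitespace-separated text matrix; `write_height_map()` writes the
#' text dialect at full precision so that write-then-read is the identity.
#'
#' @param path raster file. Extensions `.tif`/`.tiff` are read as TIFF,
#'   anything else as a text matrix.
#' @param pixel_size um per pixel.
#' @param origin um position of the raster corner.
#' @param scale multiplier applied to raw TIFF values to obtain um (TIFFs
#'   are often normalized on read).
#' @return a [height_field()].
#' @export
read_height_map <- function(path, pixel_size, origin = c(0, 0), scale = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF height maps requires the 'tiff' package",
           call. = FALSE)
    v <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(v)) != 2)
      stop("format error: height map raster is not a single-channel 2D image",
           call. = FALSE)
    v <- v * scale
  } else {
    v <- as.matrix(utils::read.table(path))
    dimnames(v) <- NULL
    if (!is.numeric(v)) stop("format error: non-numeric raster", call. = FALSE)
  }
  height_field(v, pixel_size, origin)
}

#' @rdname read_height_map
#' @param h a [height_field()].
#' @export
write_height_map <- function(h, path) {
  stopifnot(inherits(h, "height_field"))
  utils::write.table(format(h$values, digits = 15, scientific = TRUE,
                            trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
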