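#' Wrap a grayscale plate image with its grid geometry
#'
#' @param pixels Numeric matrix of intensities (rows x cols of pixels).
#' @param rows,cols Colony-array dimensions (grid cells).
#' @param origin `c(row_offset, col_offset)` in pixels of the top-left
#'   corner of the grid (0 means the grid starts at pixel 1).
#' @param pitch Cell pitch in pixels (cells are `pitch` x `pitch`).
#' @return A list of class `plate_image` with elements `pixels` and
#'   `grid`.
#' @export
plate_image <- function(pixels, rows, cols, origin = c(0L, 0L), pitch) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  rows <- as.integer(rows); cols <- as.integer(cols)
  origin <- as.integer(origin); pitch <- as.integer(pitch)
  if (origin[1L] + rows * pitch > nrow(pixels) ||
      origin[2L] + cols * pitch > ncol(pixels) || any(origin < 0L))
    stop("grid outside image bounds")
  structure(list(pixels = pixels,
                 grid = list(rows = rows, cols = cols,
                             origin = origin, pitch = pitch)),
            class = "plate_image")
}

#' Read a PNG or TIFF plate image as a grayscale matrix
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix of intensities in \[0, 1\].
#' @export
read_plate_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img
}

# Deterministic two-means (Ridler-Calvard style) global threshold for a
# bimodal intensity histogram: midpoint of the two cluster centers.
.bimodal_threshold <- function(px) {
  px <- as.numeric(px)
  if (diff(range(px)) == 0) return(max(px))  # flat image: nothing above
  km <- stats::kmeans(px, centers = matrix(range(px), ncol = 1L))
  mean(km$centers)
}

#' Quantify colony sizes on a gridded plate image
#'
#' Foreground is separated from the agar background by one global
#' per-plate intensity threshold (two-means split of the intensity
#' histogram unless given). Colony size in a cell is the number of
#' foreground pixels inside that cell's window; `measure = "intensity"`
#' instead sums background-subtracted foreground intensities.
#'
#' @param image A `plate_image`.
#' @param threshold Optional numeric threshold; pixels strictly above it
#'   are foreground.
#' @param measure `"area"` (pixel count, default) or `"intensity"`.
#' @param plate Plate identifier stored in the output.
#' @return A `data.frame` (class `colony_table`) with one row per grid
#'   cell: `plate`, `row`, `col`, `raw_size`, `normalized_size` (NA until
#'   [normalize_plate()]).
#' @examples
#' px <- matrix(0, 20, 20)
#' px[3:6, 3:6] <- 1
#' img <- plate_image(px, rows = 2, cols = 2, pitch = 10)
#' quantify_plate(img)
#' @export
quantify_plate <- function(image, threshold = NULL,
                           measure = c("area", "intensity"), plate = 1L) {
  stopifnot(inherits(image, "plate_image"))
  measure <- match.arg(measure)
  g <- image$grid
  px <- image$pixels
  if (is.null(threshold)) threshold <- .bimodal_threshold(px)
  cells <- expand.grid(row = seq_len(g$rows), col = seq_len(g$cols))
  raw <- vapply(seq_len(nrow(cells)), function(k) {
    r0 <- g$origin[1L] + (cells$row[k] - 1L) * g$pitch
    c0 <- g$origin[2L] + (cells$col[k] - 1L) * g$pitch
    win <- px[(r0 + 1L):(r0 + g$pitch), (c0 + 1L):(c0 + g$pitch)]
    fg <- win > threshold
    if (measure == "area") sum(fg) else sum(win[fg] - threshold)
  }, numeric(1))
  out <- data.frame(plate = plate, row = cells$row, col = cells$col,
                    raw_size = raw, normalized_size = NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("colony_table", "data.frame")
  out
}

#' Normalize colony sizes by the plate median
#'
#' Divides each colony's raw size by the median raw size over the
#' nonzero colonies of its plate, making sizes comparable across plates.
#' Zero colonies stay zero.
#'
#' @param table A `colony_table` with `raw_size` (may span several
#'   plates; normalization is per plate).
#' @return The table with `normalized_size` filled in.
#' @export
normalize_plate <- function(table) {
  stopifnot(is.data.frame(table), "raw_size" %in% names(table))
  if (any(table$raw_size < 0)) stop("negative colony sizes")
  for (p in unique(table$plate)) {
    i <- table$plate == p
    nz <- table$raw_size[i] > 0
    if (!any(nz)) stop("empty plate: ", p)
    table$normalized_size[i] <- table$raw_size[i] / stats::median(table$raw_size[i][nz])
  }
  if (!inherits(table, "colony_table"))
    class(table) <- c("colony_table", class(table))
  table
}

#' Attach cross identities to quantified colonies via the plate layout
#'
#' @param table A `colony_table` from [quantify_plate()].
#' @param layout A `plate_layout` from [layout_plates()]. BORDER
#'   positions are dropped.
#' @return The colony table restricted to assigned positions, with
#'   `cross_id`, `replicate`, `bait`, `prey`, `background` columns.
#' @export
assign_colonies <- function(table, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  m <- merge(as.data.frame(table),
             as.data.frame(layout)[, c("plate", "row", "col", "cross_id",
                                       "replicate", "bait", "prey",
                                       "background", "role")],
             by = c("plate", "row", "col"))
  m <- m[m$role == "cross", setdiff(names(m), "role")]
  rownames(m) <- NULL
  class(m) <- c("colony_table", "data.frame")
  m
}
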