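#' Encoder configuration
#'
#' Settings shared by the three record-to-image encoders.  The bar-graph
#' geometry follows the width formula `psi * d + gamma * (d + 1)`: `d` bars
#' of width `psi` pixels separated (and flanked) by gaps of `gamma` pixels.
#' With the defaults `psi = 1`, `gamma = 2` the image side is `3d + 2`,
#' i.e. approximately `3d`.
#'
#' @param method `"bar"` (equidistant bar graph), `"dist"` (normalized
#'   distance matrix) or `"combined"` (3-channel stack of both plus a
#'   row-wise copy of the record).
#' @param px pixel-width variant for the bars: 1, 2 or 4 (`px1`/`px2`/`px4`).
#'   Sets `psi`; the gap `gamma` stays fixed.
#' @param psi bar width in pixels (defaults to `px`).
#' @param gamma gap between consecutive bars, in pixels.
#' @param upscale integer pixel-replication factor for the distance matrix
#'   (default 3, mapping a `d x d` matrix to `3d x 3d`).
#' @param field_order optional permutation of `1..d` (or a
#'   [field_ordering()] object) applied to the record before encoding, so
#'   related fields sit in adjacent bars.
#' @return an object of class `"encoding_config"`.
#' @export
encoding_config <- function(method = c("bar", "dist", "combined"),
                            px = 1L, psi = px, gamma = 2L, upscale = 3L,
                            field_order = NULL) {
  method <- match.arg(method)
  if (!px %in% c(1L, 2L, 4L)) stop("px must be 1, 2 or 4")
  psi <- as.integer(psi); gamma <- as.integer(gamma)
  upscale <- as.integer(upscale)
  stopifnot(psi >= 1L, gamma >= 0L, upscale >= 1L)
  if (inherits(field_order, "field_ordering")) field_order <- field_order$order
  if (!is.null(field_order)) field_order <- as.integer(field_order)
  structure(list(method = method, px = as.integer(px), psi = psi,
                 gamma = gamma, upscale = upscale, field_order = field_order),
            class = "encoding_config")
}

#' @export
print.encoding_config <- function(x, ...) {
  cat(sprintf("<encoding_config> method=%s psi=%d gamma=%d upscale=%d%s\n",
              x$method, x$psi, x$gamma, x$upscale,
              if (is.null(x$field_order)) "" else " (field order set)"))
  invisible(x)
}

new_encoded_image <- function(pixels, method, source_row = NA_integer_) {
  if (length(dim(pixels)) == 2L) pixels <- array(pixels, c(dim(pixels), 1L))
  structure(list(pixels = pixels, channels = dim(pixels)[3L],
                 source_row = source_row, method = method),
            class = "encoded_image")
}

#' @export
print.encoded_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<encoded_image> %dx%dx%d (%s), intensities [%.3f, %.3f]\n",
              d[1L], d[2L], d[3L], x$method,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.encoded_image <- function(x) dim(x$pixels)

check_record <- function(x, d_min) {
  x <- as.numeric(x)
  if (length(x) < d_min)
    stop("record must have at least ", d_min, " features")
  if (anyNA(x) || min(x) < 0 || max(x) > 1)
    stop("record values must be normalized to [0, 1]")
  x
}

apply_field_order <- function(x, cfg) {
  if (is.null(cfg$field_order)) return(x)
  ord <- cfg$field_order
  if (length(ord) != length(x) || !setequal(ord, seq_along(x)))
    stop("field_order must be a permutation of 1..d")
  x[ord]
}

#' Bar-graph width for a given feature count
#'
#' Evaluates `psi * d + gamma * (d + 1)`, the pixel width (and height) of
#' the equidistant bar-graph image.
#'
#' @param d number of features.
#' @param psi bar width in pixels.
#' @param gamma gap width in pixels.
#' @export
bar_graph_width <- function(d, psi = 1L, gamma = 2L) {
  as.integer(psi) * as.integer(d) + as.integer(gamma) * (as.integer(d) + 1L)
}

#' Encode a record as an equidistant bar graph
#'
#' Each feature becomes a vertical bar of width `psi` pixels, bars
#' separated by `gamma`-pixel gaps, drawn bottom-up with height
#' `round(x_k * W)` where `W` is the image width.  The height equals the
#' width, giving a square binary image (foreground 1, background 0).
#'
#' @param x numeric record with every value in `[0, 1]`.
#' @param cfg an [encoding_config()].
#' @param source_row record index recorded for provenance.
#' @return an [`encoded_image`][encoding_config] with one channel.
#' @examples
#' img <- encode_bar_graph(c(0.2, 0.8, 0.5), encoding_config("bar"))
#' dim(img)
#' @export
encode_bar_graph <- function(x, cfg = encoding_config("bar"),
                             source_row = NA_integer_) {
  x <- check_record(x, 1L)
  x <- apply_field_order(x, cfg)
  d <- length(x)
  w <- bar_graph_width(d, cfg$psi, cfg$gamma)
  img <- matrix(0, w, w)
  heights <- round(x * w)
  for (k in seq_len(d)) {
    if (heights[k] < 1L) next
    col0 <- cfg$gamma + (k - 1L) * (cfg$psi + cfg$gamma)  # 0-based
    cols <- (col0 + 1L):(col0 + cfg$psi)
    rows <- (w - heights[k] + 1L):w                        # bottom-up
    img[rows, cols] <- 1
  }
  new_encoded_image(img, "bar", source_row)
}

#' Encode a record as a normalized distance matrix
#'
#' Pixel `(i, j)` is the Euclidean distance `|x_i - x_j|` between scalar
#' features, divided by the per-image maximum so intensities span
#' `[0, 1]` (an all-constant record yields an all-zero image).  The
#' `d x d` matrix is upscaled by pixel replication (`cfg$upscale`,
#' default 3, giving `3d x 3d`).
#'
#' @inheritParams encode_bar_graph
#' @export
encode_distance_matrix <- function(x, cfg = encoding_config("dist"),
                                   source_row = NA_integer_) {
  x <- check_record(x, 2L)
  x <- apply_field_order(x, cfg)
  m <- abs(outer(x, x, "-"))
  mx <- max(m)
  if (mx > 0) m <- m / mx
  if (cfg$upscale > 1L)
    m <- kronecker(m, matrix(1, cfg$upscale, cfg$upscale))
  new_encoded_image(m, "dist", source_row)
}

# Nearest-neighbour resample of a square matrix to side `side`.  Used to
# fit the bar graph's native width into the combined image's 3d grid; when
# the native width is side + 2 this reduces to a symmetric 1-pixel crop.
resample_square <- function(m, side) {
  w <- nrow(m)
  if (w == side) return(m)
  if (w == side + 2L) return(m[2:(w - 1L), 2:(w - 1L)])
  idx <- pmin(w, floor((seq_len(side) - 0.5) * w / side) + 1L)
  m[idx, idx]
}

#' Encode a record as a 3-channel combined image
#'
#' Stacks the three views of one record into a `3d x 3d x 3` color image:
#' channel 1 the distance matrix upscaled 3x, channel 2 the bar graph
#' resampled to `3d x 3d` (a symmetric 1-pixel crop when `psi = 1`,
#' `gamma = 2`, whose native width is `3d + 2`), and channel 3 a row-wise
#' copy of the record in which pixel rows `3i-2..3i` are constant at
#' `x_i`.
#'
#' @inheritParams encode_bar_graph
#' @export
encode_combined <- function(x, cfg = encoding_config("combined"),
                            source_row = NA_integer_) {
  x <- check_record(x, 2L)
  x <- apply_field_order(x, cfg)
  d <- length(x)
  side <- 3L * d
  sub <- encoding_config(method = "combined", px = cfg$px, psi = cfg$psi,
                         gamma = cfg$gamma, upscale = 3L)
  ch1 <- encode_distance_matrix(x, sub)$pixels[, , 1L]
  bar <- encode_bar_graph(x, sub)$pixels[, , 1L]
  ch2 <- resample_square(bar, side)
  ch3 <- matrix(rep(x, each = 3L), nrow = side, ncol = side)
  new_encoded_image(array(c(ch1, ch2, ch3), c(side, side, 3L)),
                    "combined", source_row)
}

#' Encode one record with the configured method
#'
#' @inheritParams encode_bar_graph
#' @export
encode_record <- function(x, cfg, source_row = NA_integer_) {
  switch(cfg$method,
         bar = encode_bar_graph(x, cfg, source_row),
         dist = encode_distance_matrix(x, cfg, source_row),
         combined = encode_combined(x, cfg, source_row))
}

# Encode every row of a normalized dataset into a (H, W, C, N) array.
encode_array <- function(ds, cfg) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (!ds$normalized) stop("normalize the dataset before encoding")
  n <- n_records(ds)
  first <- encode_record(ds$features[1L, ], cfg, 1L)
  dims <- dim(first$pixels)
  out <- array(0, c(dims, n))
  out[, , , 1L] <- first$pixels
  if (n > 1L) for (i in 2:n)
    out[, , , i] <- encode_record(ds$features[i, ], cfg, i)$pixels
  out
}

#' Encode a whole dataset to image files
#'
#' Writes one PNG per record (8-bit grayscale for the bar-graph and
#' distance-matrix encoders, RGB for the combined encoder) plus a
#' `manifest.csv` with columns `filename`, `row`, `label`.
#'
#' @param ds a normalized `tabular_dataset`.
#' @param cfg an [encoding_config()].
#' @param out_dir output directory, created if needed.
#' @return the manifest as a data frame, invisibly.
#' @export
encode_dataset <- function(ds, cfg, out_dir) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  n <- n_records(ds)
  manifest <- data.frame(filename = character(n), row = integer(n),
                         label = integer(n))
  for (i in seq_len(n)) {
    img <- encode_record(ds$features[i, ], cfg, i)
    px <- if (img$channels == 1L) img$pixels[, , 1L] else img$pixels
    fn <- sprintf("%s_%05d.png", cfg$method, i)
    png::writePNG(px, file.path(out_dir, fn))
    manifest[i, ] <- list(fn, i, ds$labels[i])
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read an encoded dataset back from disk
#'
#' @param dir directory written by [encode_dataset()].
#' @return list with `images` (H, W, C, N array) and `labels`.
#' @export
read_encoded_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  first <- png::readPNG(file.path(dir, manifest$filename[1L]))
  if (length(dim(first)) == 2L) first <- array(first, c(dim(first), 1L))
  out <- array(0, c(dim(first), nrow(manifest)))
  out[, , , 1L] <- first
  if (nrow(manifest) > 1L) for (i in 2:nrow(manifest)) {
    p <- png::readPNG(file.path(dir, manifest$filename[i]))
    if (length(dim(p)) == 2L) p <- array(p, c(dim(p), 1L))
    out[, , , i] <- p
  }
  list(images = out, labels = manifest$label)
}
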