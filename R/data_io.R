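# Manifest reading, tail cropping, dataset splitting and image
# preprocessing.
#
# Coordinate convention everywhere: 0-based, half-open boxes
# [x0, x1) x [y0, y1), x along image columns, y along rows, so width is
# x1 - x0 and height is y1 - y0 with no off-by-one ambiguity.

MANIFEST_COLUMNS <- c("path", "x0", "y0", "x1", "y1", "bcs")

# Channel normalization constants of the standard pretrained-backbone input
# pipeline (RGB means and standard deviations on the 0-1 scale).
IMAGE_MEAN <- c(0.485, 0.456, 0.406)
IMAGE_SD <- c(0.229, 0.224, 0.225)

#' Read and validate a dataset manifest
#'
#' The manifest is a CSV with header `path,x0,y0,x1,y1,bcs`. Structural
#' invariants (column set, unique paths, legal BCS labels, well-formed
#' boxes) are validated eagerly; box-versus-image-bounds checks happen when
#' pixels are actually cropped.
#'
#' @param path manifest file path.
#' @return data.frame of image records, one per row.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  m <- m[, MANIFEST_COLUMNS]
  if (anyDuplicated(m$path))
    stop("manifest row ", anyDuplicated(m$path), ": duplicate path ",
         m$path[anyDuplicated(m$path)])
  for (i in seq_len(nrow(m))) {
    if (min(abs(m$bcs[i] - bcs_levels())) > 1e-9)
      stop("manifest row ", i, ": BCS label ", m$bcs[i],
           " is not one of ", paste(bcs_levels(), collapse = ", "))
    if (!is.finite(m$x0[i]) || !is.finite(m$x1[i]) ||
        !is.finite(m$y0[i]) || !is.finite(m$y1[i]) ||
        m$x0[i] >= m$x1[i] || m$y0[i] >= m$y1[i] || m$x0[i] < 0 || m$y0[i] < 0)
      stop("manifest row ", i, ": malformed bbox (",
           m$x0[i], ",", m$y0[i], ",", m$x1[i], ",", m$y1[i], ")")
  }
  m
}

#' Crop the tail region from an image
#'
#' @param pixels image array `(H, W, C)` (or `(H, W)`).
#' @param bbox `c(x0, y0, x1, y1)`, 0-based half-open pixel coordinates.
#' @return the `(y1-y0) x (x1-x0)` sub-image.
#' @export
crop_tail <- function(pixels, bbox) {
  bbox <- as.numeric(bbox)
  x0 <- bbox[1]; y0 <- bbox[2]; x1 <- bbox[3]; y1 <- bbox[4]
  d <- dim(pixels)
  if (x0 >= x1 || y0 >= y1) stop("empty bbox: width and height must be positive")
  if (x0 < 0 || y0 < 0 || x1 > d[2] || y1 > d[1])
    stop("bbox (", x0, ",", y0, ",", x1, ",", y1, ") outside image bounds ",
         d[2], "x", d[1])
  if (length(d) == 3) pixels[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  else pixels[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
}

#' Split a dataset 7:2:1
#'
#' Shuffles `0..n-1` with the seed, then takes `floor(r1 * n)` indices for
#' training, the next `floor(r2 * n)` for validation, and the remainder for
#' testing. Sizes depend only on `n` and the ratios; membership only on the
#' seed.
#'
#' @param n number of items (>= 3).
#' @param ratios length-3 vector summing to 1 (default `c(0.7, 0.2, 0.1)`).
#' @param seed shuffle seed.
#' @return list with integer index vectors `train`, `val`, `test`
#'   (0-based, pairwise disjoint, covering `0..n-1`).
#' @export
split_dataset <- function(n, ratios = c(0.7, 0.2, 0.1), seed = 42L) {
  if (n < 3) stop("n must be >= 3 to populate all three splits")
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be three values summing to 1")
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(n) - 1L
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[(n_train + n_val + 1):n])
}

#' Bilinear image resize
#'
#' Half-pixel-centered bilinear interpolation (the convention of standard
#' image pipelines, no corner alignment).
#'
#' @param img array `(H, W)` or `(H, W, C)`.
#' @param out_h,out_w output size.
#' @return resized array.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  if (h == out_h && w == out_w) return(img)
  src <- function(i, n_out, n_in) pmin(pmax((i - 0.5) * n_in / n_out - 0.5, 0), n_in - 1)
  ys <- src(seq_len(out_h), out_h, h)
  xs <- src(seq_len(out_w), out_w, w)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- ys - y0; wx <- xs - x0
  interp_plane <- function(p) {
    a <- p[cbind(rep(y0 + 1, times = out_w), rep(x0 + 1, each = out_h))]
    b <- p[cbind(rep(y0 + 1, times = out_w), rep(x1 + 1, each = out_h))]
    cc <- p[cbind(rep(y1 + 1, times = out_w), rep(x0 + 1, each = out_h))]
    dd <- p[cbind(rep(y1 + 1, times = out_w), rep(x1 + 1, each = out_h))]
    wyf <- rep(wy, times = out_w); wxf <- rep(wx, each = out_h)
    v <- (a * (1 - wyf) + cc * wyf) * (1 - wxf) + (b * (1 - wyf) + dd * wyf) * wxf
    matrix(v, out_h, out_w)
  }
  if (length(d) == 2) return(interp_plane(img))
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- interp_plane(img[, , ch])
  out
}

#' Preprocess an image into a network input
#'
#' Resizes to `input_size x input_size`, scales intensities to `[0, 1]`
#' (0-255 inputs are detected and divided by 255) and normalizes each
#' channel by the standard RGB mean/sd constants (means 0.485, 0.456, 0.406;
#' sds 0.229, 0.224, 0.225).
#'
#' @param pixels RGB array `(H, W, 3)`.
#' @param input_size target square size (default 224).
#' @return normalized array `(input_size, input_size, 3)`.
#' @export
preprocess <- function(pixels, input_size = 224L) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3)
    stop("preprocess expects an RGB image with dim (H, W, 3)")
  if (d[1] < 1 || d[2] < 1) stop("empty image")
  if (max(pixels) > 1.5) pixels <- pixels / 255
  out <- bilinear_resize(pixels, input_size, input_size)
  for (ch in 1:3) out[, , ch] <- (out[, , ch] - IMAGE_MEAN[ch]) / IMAGE_SD[ch]
  out
}

#' Load, crop and preprocess a manifest into arrays
#'
#' @param manifest data.frame from [read_manifest()] (or [generate_dataset()]).
#' @param dir directory containing the images.
#' @param input_size network input size.
#' @param normalize apply the channel normalization of [preprocess()];
#'   set `FALSE` to keep raw `[0, 1]` intensities.
#' @return list with `x` (`input_size x input_size x 3 x N`), `y` (0-based
#'   class indices) and `labels` (BCS values).
#' @export
load_dataset <- function(manifest, dir, input_size = 32L, normalize = FALSE) {
  n <- nrow(manifest)
  x <- array(0, c(input_size, input_size, 3, n))
  y <- integer(n)
  for (i in seq_len(n)) {
    px <- png::readPNG(file.path(dir, manifest$path[i]))
    if (length(dim(px)) == 3 && dim(px)[3] > 3) px <- px[, , 1:3]
    crop <- crop_tail(px, c(manifest$x0[i], manifest$y0[i],
                            manifest$x1[i], manifest$y1[i]))
    x[, , , i] <- if (normalize) preprocess(crop, input_size)
                  else bilinear_resize(crop, input_size, input_size)
    y[i] <- which.min(abs(manifest$bcs[i] - bcs_levels())) - 1L
  }
  list(x = x, y = y, labels = bcs_levels()[y + 1L])
}
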