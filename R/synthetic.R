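# Class-conditional synthetic tail images.
#
# The generator encodes the single feature the scoring method relies on: the
# depth of the depression flanking the tail root, which decreases
# monotonically as body condition improves (lean cow -> deep, shadowed
# depression; fat cow -> flat tail root). Nuisance variation is additive
# pixel noise and a multiplicative brightness jitter. Everything else about
# real farm imagery (breed, pose, background clutter) is out of scope.

#' Specification of the synthetic tail-image corpus
#'
#' @param image_size square image side in pixels before cropping (default 256,
#'   so that bbox cropping and resizing are real operations).
#' @param n_per_class images per BCS class.
#' @param seed integer seed; the corpus is a pure function of the spec.
#' @param depression_depths five strictly monotone values in `[0, 1]`, the
#'   shading intensity of the tail-root depression per class (class order is
#'   lean to fat, so depths decrease; defaults 0.9, 0.7, 0.5, 0.3, 0.1).
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity scale 0-1).
#' @param lighting_jitter half-width of the multiplicative brightness range;
#'   each image is scaled by a factor drawn from
#'   `U(1 - lighting_jitter, 1 + lighting_jitter)`.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(image_size = 256L, n_per_class = 20L, seed = 42L,
                           depression_depths = c(0.9, 0.7, 0.5, 0.3, 0.1),
                           noise_sd = 0.05, lighting_jitter = 0.1) {
  if (length(depression_depths) != 5)
    stop("depression_depths must have five values, one per BCS class")
  dd <- diff(depression_depths)
  if (!(all(dd > 0) || all(dd < 0)))
    stop("depression_depths must be strictly monotone across classes")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (image_size < 32) stop("image_size must be >= 32")
  structure(list(image_size = as.integer(image_size),
                 n_per_class = as.integer(n_per_class), seed = as.integer(seed),
                 depression_depths = depression_depths, noise_sd = noise_sd,
                 lighting_jitter = lighting_jitter),
            class = "synthetic_spec")
}

# Mix the corpus seed and the per-item seed into one 31-bit stream seed.
item_stream_seed <- function(seed, item_seed) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(item_seed) * 16807) %% 2147483587)
}

#' Generate one synthetic tail image
#'
#' Draws a cattle rear as a bright body region, a vertical elongated tail,
#' and two flanking tail-root depressions whose darkness is
#' `depression_depths[class_index + 1]`, then applies brightness jitter and
#' additive Gaussian noise. The bounding box tightly contains the tail
#' structure (tail plus depressions).
#'
#' @param class_index BCS class, 0 to 4 (lean to fat).
#' @param spec a [synthetic_spec()].
#' @param item_seed integer; together with `spec$seed` it makes the image a
#'   pure function of its arguments.
#' @return list with `pixels` (`image_size x image_size x 3`, values in
#'   `[0, 1]`), `bbox` (`c(x0, y0, x1, y1)`, 0-based half-open pixel
#'   coordinates) and `label` (the class's BCS value).
#' @export
generate_tail_image <- function(class_index, spec = synthetic_spec(),
                                item_seed = 0L) {
  if (length(class_index) != 1 || is.na(class_index) ||
      class_index %% 1 != 0 || class_index < 0 || class_index > 4)
    stop("class_index must be an integer in 0..4")
  s <- spec$image_size
  depth <- spec$depression_depths[class_index + 1L]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(item_stream_seed(spec$seed, item_seed * 5L + class_index))

  xg <- matrix(rep(seq_len(s), each = s), s, s)   # column index
  yg <- matrix(rep(seq_len(s), times = s), s, s)  # row index

  # scene geometry (pixels), jittered per image
  cx <- s / 2 + stats::runif(1, -0.04, 0.04) * s
  ty0 <- s * (0.22 + stats::runif(1, -0.03, 0.03))   # tail-root top
  tail_len <- s * (0.5 + stats::runif(1, -0.05, 0.05))
  tail_w <- s * (0.05 + stats::runif(1, -0.008, 0.008))
  dep_w <- s * (0.085 + stats::runif(1, -0.01, 0.01))
  dep_h <- s * (0.16 + stats::runif(1, -0.02, 0.02))
  dep_cy <- ty0 + dep_h * 0.55

  body_i <- 0.68 + stats::runif(1, -0.03, 0.03)
  bg_i <- 0.35 + stats::runif(1, -0.05, 0.05)

  # intensity map: background with vertical gradient, body disc, tail, depressions
  int <- bg_i + 0.08 * (yg / s - 0.5)
  body_mask <- ((xg - s / 2)^2 / (0.42 * s)^2 + (yg - s * 0.55)^2 / (0.45 * s)^2) <= 1
  int[body_mask] <- body_i
  tail_mask <- abs(xg - cx) <= tail_w / 2 & yg >= ty0 & yg <= ty0 + tail_len
  int[tail_mask] <- body_i * 0.82
  # two flanking depressions; darkness scales with class depth
  for (side in c(-1, 1)) {
    dcx <- cx + side * (tail_w / 2 + dep_w / 2 + 1)
    dmask <- ((xg - dcx)^2 / (dep_w / 2)^2 + (yg - dep_cy)^2 / (dep_h / 2)^2) <= 1
    # smooth falloff toward the rim of the depression
    r2 <- pmin(((xg - dcx)^2 / (dep_w / 2)^2 + (yg - dep_cy)^2 / (dep_h / 2)^2), 1)
    shade <- body_i * (1 - 0.65 * depth * (1 - r2))
    int[dmask] <- shade[dmask]
  }

  factor <- if (spec$lighting_jitter > 0)
    stats::runif(1, 1 - spec$lighting_jitter, 1 + spec$lighting_jitter) else 1
  tint <- c(1.0, 0.94, 0.86)
  pixels <- array(0, c(s, s, 3))
  for (ch in 1:3) {
    layer <- int * tint[ch] * factor
    if (spec$noise_sd > 0)
      layer <- layer + stats::rnorm(s * s, sd = spec$noise_sd)
    pixels[, , ch] <- pmin(pmax(layer, 0), 1)
  }

  x0 <- max(0L, as.integer(floor(cx - tail_w / 2 - dep_w - 3)))
  x1 <- min(s, as.integer(ceiling(cx + tail_w / 2 + dep_w + 3)))
  y0 <- max(0L, as.integer(floor(ty0 - 3)))
  y1 <- min(s, as.integer(ceiling(ty0 + tail_len + 3)))
  list(pixels = pixels, bbox = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
       label = bcs_levels()[class_index + 1L])
}

# Region used by the monotone-feature diagnostics: the two depression
# ellipses cannot be recovered exactly post hoc, so use the bbox band around
# the tail root excluding the tail column itself.
depression_region_mean <- function(img) {
  px <- img$pixels; b <- img$bbox
  rows <- (b["y0"] + 1):(b["y0"] + round((b["y1"] - b["y0"]) * 0.35))
  cols <- (b["x0"] + 1):b["x1"]
  cx <- (b["x0"] + b["x1"]) / 2
  keep <- abs(cols - cx) > (b["x1"] - b["x0"]) * 0.12
  mean(px[rows, cols[keep], ])
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_per_class * 5` PNG images plus a CSV manifest with columns
#' `path,x0,y0,x1,y1,bcs`. Class counts are exactly balanced and the output
#' is a pure function of the spec.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return the manifest as a data.frame (invisibly also written to
#'   `manifest.csv` in `out_dir`).
#' @export
generate_dataset <- function(spec = synthetic_spec(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", spec$n_per_class * 5L)
  k <- 0
  for (ci in 0:4) {
    for (i in seq_len(spec$n_per_class)) {
      img <- generate_tail_image(ci, spec, item_seed = i)
      rel <- sprintf("bcs%03d_item%04d.png", round(bcs_levels()[ci + 1] * 100), i)
      png::writePNG(img$pixels, file.path(out_dir, rel))
      k <- k + 1
      rows[[k]] <- data.frame(path = rel, x0 = img$bbox[["x0"]],
                              y0 = img$bbox[["y0"]], x1 = img$bbox[["x1"]],
                              y1 = img$bbox[["y1"]], bcs = img$label)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}

#' Generate an in-memory training corpus
#'
#' Convenience path used by the training and evaluation examples: images are
#' generated, cropped to their tail bounding box and resized to
#' `input_size`, without touching the disk.
#'
#' @param spec a [synthetic_spec()].
#' @param input_size square network input size.
#' @param normalize apply the standard channel normalization of
#'   [preprocess()] (recommended for training; raw `[0, 1]` intensities
#'   otherwise).
#' @return list with `x` (`input_size x input_size x 3 x N` array), `y`
#'   (0-based class indices), `labels` (BCS values).
#' @export
generate_corpus <- function(spec = synthetic_spec(), input_size = 32L,
                            normalize = TRUE) {
  n <- spec$n_per_class * 5L
  x <- array(0, c(input_size, input_size, 3, n))
  y <- integer(n)
  k <- 0
  for (ci in 0:4) {
    for (i in seq_len(spec$n_per_class)) {
      img <- generate_tail_image(ci, spec, item_seed = i)
      crop <- crop_tail(img$pixels, img$bbox)
      k <- k + 1
      x[, , , k] <- if (normalize) preprocess(crop, input_size)
                    else bilinear_resize(crop, input_size, input_size)
      y[k] <- ci
    }
  }
  list(x = x, y = y, labels = bcs_levels()[y + 1L])
}
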