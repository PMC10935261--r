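#' Augmentation configuration
#'
#' Bundles the probabilities and parameter ranges of the two augmentation
#' families: the *transformation class* (rotation, horizontal flip, crop,
#' photometric jitter — each fired independently with a small per-sub-strategy
#' probability so several can combine on one image) and the *cropping class*
#' (cutout, random erasing, hide-and-seek — mutually exclusive branches of a
#' single categorical draw, so at most one occlusion is applied per image).
#'
#' @param p_sub_strategy Probability that each transformation sub-strategy
#'   fires on a given image (default 0.10).
#' @param rotation_range Maximum absolute rotation in degrees (default 30).
#' @param p_hflip Probability of actually mirroring once the flip sub-strategy
#'   has fired (default 0.50).
#' @param max_crop_frac Upper bound on the cropped-away fraction of each side
#'   (default 0.20); the crop window is resized back to the input size.
#' @param contrast_range Half-width of the photometric jitter applied to
#'   brightness, contrast, saturation and hue (default 0.10, i.e. +/- 10%).
#' @param p_cutout,p_random_erase,p_hide_and_seek Branch probabilities of the
#'   occlusion dispatcher (defaults 0.15, 0.10, 0.05; the remaining mass
#'   applies no occlusion).
#' @param occlusion_area_range Range of the occluded area as a fraction of the
#'   image area (default `c(0.10, 0.20)`).
#' @param expansion_factor How many images each source image contributes in
#'   [expand_dataset()], itself included (default 10).
#' @param hs_grid,hs_p_hide Hide-and-seek grid size per side and per-patch
#'   hiding probability (defaults 4 and 0.25).
#' @param seed Optional integer seed fixed by [expand_dataset()].
#' @return An object of class `"augment_config"`.
#' @export
augment_config <- function(p_sub_strategy = 0.10, rotation_range = 30,
                           p_hflip = 0.50, max_crop_frac = 0.20,
                           contrast_range = 0.10,
                           p_cutout = 0.15, p_random_erase = 0.10,
                           p_hide_and_seek = 0.05,
                           occlusion_area_range = c(0.10, 0.20),
                           expansion_factor = 10,
                           hs_grid = 4, hs_p_hide = 0.25,
                           seed = NULL) {
  probs <- c(p_sub_strategy, p_hflip, p_cutout, p_random_erase,
             p_hide_and_seek, hs_p_hide)
  stopifnot(
    all(is.finite(probs)), all(probs >= 0), all(probs <= 1),
    p_cutout + p_random_erase + p_hide_and_seek <= 1,
    rotation_range >= 0, max_crop_frac >= 0, max_crop_frac < 1,
    contrast_range >= 0,
    length(occlusion_area_range) == 2L,
    occlusion_area_range[1] >= 0, occlusion_area_range[2] < 1,
    occlusion_area_range[1] <= occlusion_area_range[2],
    expansion_factor >= 1, hs_grid >= 1,
    is.null(seed) || (is.numeric(seed) && length(seed) == 1L)
  )
  structure(
    list(p_sub_strategy = p_sub_strategy, rotation_range = rotation_range,
         p_hflip = p_hflip, max_crop_frac = max_crop_frac,
         contrast_range = contrast_range, p_cutout = p_cutout,
         p_random_erase = p_random_erase, p_hide_and_seek = p_hide_and_seek,
         occlusion_area_range = occlusion_area_range,
         expansion_factor = as.integer(expansion_factor),
         hs_grid = as.integer(hs_grid), hs_p_hide = hs_p_hide, seed = seed),
    class = "augment_config"
  )
}

check_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      any(dim(img)[1:2] < 1L)) {
    stop("image must be a non-empty H x W x 3 array", call. = FALSE)
  }
  if (any(!is.finite(img)) || any(img < 0) || any(img > 1)) {
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  }
  invisible(img)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# EBImage stores images x-by-y; our arrays are row (H) by column (W)
as_eb <- function(img) EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
from_eb <- function(e) clamp01(aperm(EBImage::imageData(e), c(2, 1, 3)))

# replicate-pad by `p` pixels on every side
pad_replicate <- function(img, p) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ri <- pmin(pmax(seq_len(h + 2 * p) - p, 1L), h)
  ci <- pmin(pmax(seq_len(w + 2 * p) - p, 1L), w)
  img[ri, ci, , drop = FALSE]
}

rotate_keep_size <- function(img, angle) {
  h <- dim(img)[1]; w <- dim(img)[2]
  p <- ceiling(0.3 * max(h, w))
  padded <- pad_replicate(img, p)
  e <- EBImage::rotate(as_eb(padded), angle,
                       output.dim = c(w + 2 * p, h + 2 * p),
                       filter = "bilinear")
  out <- from_eb(e)
  out[p + seq_len(h), p + seq_len(w), , drop = FALSE]
}

resize_to <- function(img, h, w) {
  from_eb(EBImage::resize(as_eb(img), w = w, h = h, filter = "bilinear"))
}

# vectorized HSV -> RGB companion to grDevices::rgb2hsv
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6); f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- i %% 6
  r[idx == 0] <- v[idx == 0]; g[idx == 0] <- t[idx == 0]; b[idx == 0] <- p[idx == 0]
  r[idx == 1] <- q[idx == 1]; g[idx == 1] <- v[idx == 1]; b[idx == 1] <- p[idx == 1]
  r[idx == 2] <- p[idx == 2]; g[idx == 2] <- v[idx == 2]; b[idx == 2] <- t[idx == 2]
  r[idx == 3] <- p[idx == 3]; g[idx == 3] <- q[idx == 3]; b[idx == 3] <- v[idx == 3]
  r[idx == 4] <- t[idx == 4]; g[idx == 4] <- p[idx == 4]; b[idx == 4] <- v[idx == 4]
  r[idx == 5] <- v[idx == 5]; g[idx == 5] <- p[idx == 5]; b[idx == 5] <- q[idx == 5]
  list(r = r, g = g, b = b)
}

color_jitter <- function(img, range) {
  if (range <= 0) return(img)
  d <- stats::runif(4, -range, range)  # brightness, contrast, saturation, hue
  img <- img + d[1]
  img <- (img - mean(img)) * (1 + d[2]) + mean(img)
  img <- clamp01(img)
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  for (ch in 1:3) img[, , ch] <- gray + (img[, , ch] - gray) * (1 + d[3])
  img <- clamp01(img)
  if (d[4] != 0) {
    hsv <- grDevices::rgb2hsv(r = as.vector(img[, , 1]),
                              g = as.vector(img[, , 2]),
                              b = as.vector(img[, , 3]), maxColorValue = 1)
    rgb <- hsv_to_rgb(hsv[1, ] + d[4], hsv[2, ], hsv[3, ])
    hw <- dim(img)[1:2]
    img <- array(c(rgb$r, rgb$g, rgb$b), c(hw, 3))
  }
  clamp01(img)
}

#' Probability-combined transformation policy
#'
#' Each of the four transformation sub-strategies — rotation (uniform within
#' `+/- rotation_range` degrees), horizontal flip, crop-and-resize (up to
#' `max_crop_frac` of each side), and photometric jitter (brightness,
#' contrast, saturation, hue within `+/- contrast_range`) — fires
#' independently with probability `p_sub_strategy`, so several can stack on
#' one image. A fired flip mirrors the image with probability `p_hflip`.
#' Output dimensions always equal the input's.
#'
#' @param img An H x W x 3 array with values in `[0, 1]`.
#' @param cfg An [augment_config()].
#' @return The transformed image, with attribute `"fired"`: a named logical
#'   vector recording which sub-strategies fired.
#' @export
apply_transform_policy <- function(img, cfg = augment_config()) {
  check_image(img); stopifnot(inherits(cfg, "augment_config"))
  h <- dim(img)[1]; w <- dim(img)[2]
  fired <- stats::runif(4) < cfg$p_sub_strategy
  names(fired) <- c("rotation", "flip", "crop", "color_jitter")
  if (fired["rotation"]) {
    angle <- stats::runif(1, -cfg$rotation_range, cfg$rotation_range)
    if (angle != 0) img <- rotate_keep_size(img, angle)
  }
  if (fired["flip"]) {
    if (stats::runif(1) < cfg$p_hflip) img <- img[, w:1, , drop = FALSE]
  }
  if (fired["crop"]) {
    u <- stats::runif(1, 0, cfg$max_crop_frac)
    ch <- max(1L, round((1 - u) * h)); cw <- max(1L, round((1 - u) * w))
    if (ch < h || cw < w) {
      top <- sample.int(h - ch + 1L, 1L); left <- sample.int(w - cw + 1L, 1L)
      img <- resize_to(img[top + seq_len(ch) - 1L, left + seq_len(cw) - 1L, ,
                           drop = FALSE], h, w)
    }
  }
  if (fired["color_jitter"]) img <- color_jitter(img, cfg$contrast_range)
  structure(clamp01(img), fired = fired)
}

draw_occlusion_area <- function(cfg) {
  stats::runif(1, cfg$occlusion_area_range[1], cfg$occlusion_area_range[2])
}

#' Cutout occlusion
#'
#' Zeros one axis-aligned square whose area is drawn uniformly from
#' `occlusion_area_range` times the image area; the square lies fully inside
#' the image and all other pixels are untouched.
#'
#' @inheritParams apply_transform_policy
#' @return The occluded image.
#' @export
cutout <- function(img, cfg = augment_config()) {
  check_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (round(sqrt(cfg$occlusion_area_range[2] * h * w)) > min(h, w)) {
    stop("occlusion area range infeasible for this image size", call. = FALSE)
  }
  a <- draw_occlusion_area(cfg)
  side <- round(sqrt(a * h * w))
  if (side < 1) return(img)
  top <- sample.int(h - side + 1L, 1L); left <- sample.int(w - side + 1L, 1L)
  img[top + seq_len(side) - 1L, left + seq_len(side) - 1L, ] <- 0
  img
}

#' Random-erasing occlusion
#'
#' Fills one rectangle — area drawn uniformly from `occlusion_area_range`
#' times the image area, aspect ratio log-uniform in `[1/3, 3]` — with
#' independent uniform noise in `[0, 1]`.
#'
#' @inheritParams apply_transform_policy
#' @return The occluded image.
#' @export
random_erase <- function(img, cfg = augment_config()) {
  check_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (round(sqrt(cfg$occlusion_area_range[2] * h * w)) > min(h, w)) {
    stop("occlusion area range infeasible for this image size", call. = FALSE)
  }
  a <- draw_occlusion_area(cfg)
  if (a <= 0) return(img)
  for (attempt in 1:50) {
    r <- exp(stats::runif(1, log(1 / 3), log(3)))  # aspect = width / height
    eh <- round(sqrt(a * h * w / r)); ew <- round(sqrt(a * h * w * r))
    if (eh >= 1 && ew >= 1 && eh <= h && ew <= w) break
    if (attempt == 50) { eh <- round(sqrt(a * h * w)); ew <- eh }
  }
  top <- sample.int(h - eh + 1L, 1L); left <- sample.int(w - ew + 1L, 1L)
  img[top + seq_len(eh) - 1L, left + seq_len(ew) - 1L, ] <-
    stats::runif(eh * ew * 3)
  clamp01(img)
}

#' Hide-and-seek occlusion
#'
#' Divides the image into `grid` x `grid` patches and independently zeros each
#' patch with probability `p_hide`.
#'
#' @inheritParams apply_transform_policy
#' @param grid Patches per side (default 4).
#' @param p_hide Per-patch hiding probability (default 0.25).
#' @return The occluded image.
#' @export
hide_and_seek <- function(img, grid = 4, p_hide = 0.25) {
  check_image(img)
  if (!is.numeric(grid) || grid < 1) stop("`grid` must be >= 1", call. = FALSE)
  grid <- as.integer(grid)
  h <- dim(img)[1]; w <- dim(img)[2]
  rb <- round(seq(0, h, length.out = grid + 1L))
  cb <- round(seq(0, w, length.out = grid + 1L))
  hide <- matrix(stats::runif(grid * grid) < p_hide, grid, grid)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      if (hide[i, j] && rb[i + 1] > rb[i] && cb[j + 1] > cb[j]) {
        img[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L], ] <- 0
      }
    }
  }
  img
}

#' Cropping-class occlusion dispatcher
#'
#' A single categorical draw selects at most one occlusion per image:
#' cutout with probability `p_cutout`, random erasing with `p_random_erase`,
#' hide-and-seek with `p_hide_and_seek`, and no occlusion with the remaining
#' mass.
#'
#' @inheritParams apply_transform_policy
#' @return The (possibly) occluded image, with attribute `"occlusion"` naming
#'   the branch taken: `"cutout"`, `"random_erase"`, `"hide_and_seek"` or
#'   `"none"`.
#' @export
apply_occlusion_policy <- function(img, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  u <- stats::runif(1)
  cuts <- cumsum(c(cfg$p_cutout, cfg$p_random_erase, cfg$p_hide_and_seek))
  branch <- if (u < cuts[1]) "cutout"
            else if (u < cuts[2]) "random_erase"
            else if (u < cuts[3]) "hide_and_seek"
            else "none"
  out <- switch(branch,
    cutout = cutout(img, cfg),
    random_erase = random_erase(img, cfg),
    hide_and_seek = hide_and_seek(img, cfg$hs_grid, cfg$hs_p_hide),
    none = check_image(img)
  )
  structure(out, occlusion = branch)
}

#' Expand a labeled dataset by stochastic augmentation
#'
#' Each source image contributes itself plus `expansion_factor - 1` augmented
#' variants; every variant first passes [apply_transform_policy()], then one
#' occlusion branch is selected by [apply_occlusion_policy()]. Labels are
#' preserved, so per-class counts scale exactly by the expansion factor.
#'
#' @param items List of labeled images (`list(image =, label =, id =)`), as
#'   produced by [generate_synthetic_dataset()] or [read_image_folder()].
#' @param cfg An [augment_config()]; `cfg$seed`, when set, makes the expansion
#'   reproducible.
#' @return A list of `expansion_factor * length(items)` labeled images; the
#'   variants' ids carry an `_augNN` suffix.
#' @export
expand_dataset <- function(items, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  if (length(items) == 0L) stop("`items` must be non-empty", call. = FALSE)
  if (cfg$expansion_factor < 1L) stop("`expansion_factor` must be >= 1", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$expansion_factor == 1L) return(items)
  out <- vector("list", length(items) * cfg$expansion_factor)
  k <- 0L
  for (item in items) {
    k <- k + 1L
    out[[k]] <- item
    for (v in seq_len(cfg$expansion_factor - 1L)) {
      img <- apply_transform_policy(item$image, cfg)
      img <- apply_occlusion_policy(img, cfg)
      attributes(img) <- list(dim = dim(img))
      k <- k + 1L
      out[[k]] <- list(image = img, label = item$label,
                       id = sprintf("%s_aug%02d", item$id, v))
    }
  }
  out
}
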