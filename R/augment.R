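#' @title Patch preprocessing and augmentation
#' @description The augmentation vocabulary is deliberately restricted to
#'   the operations used for histology tiles: horizontal/vertical flips,
#'   right-angle rotations (90 and 180 degrees -- a pathologist's slide has
#'   no canonical orientation), zoom-crop, brightness/contrast/saturation
#'   jitter, and probabilistic grayscale conversion. All operators preserve
#'   shape and the \[0, 1\] value range; flips and rotations preserve the
#'   pixel multiset exactly.
#' @name augment
NULL

#' Flip a patch
#'
#' @param patch H x W x C array.
#' @param direction `"horizontal"` (mirrors columns) or `"vertical"`
#'   (mirrors rows). Both are involutions.
#' @return flipped array.
#' @export
flip_patch <- function(patch, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  if (direction == "horizontal") patch[, rev(seq_len(dim(patch)[2])), , drop = FALSE]
  else patch[rev(seq_len(dim(patch)[1])), , , drop = FALSE]
}

#' Rotate a patch by a right angle
#'
#' Counterclockwise rotation by 90 or 180 degrees only; any other angle is an
#' input-contract error (arbitrary-angle rotation would interpolate and leak
#' pixels). Four 90-degree rotations are the identity.
#'
#' @param patch H x W x C array (square for 90 degrees).
#' @param angle 90 or 180.
#' @return rotated array.
#' @export
rotate_patch <- function(patch, angle) {
  if (!angle %in% c(90, 180))
    stop("rotation angle must be 90 or 180 degrees")
  H <- dim(patch)[1]; W <- dim(patch)[2]; C <- dim(patch)[3]
  if (angle == 90) {
    # counterclockwise: out[i, j] = in[j, W + 1 - i] transposed per channel
    out <- array(0, dim = c(W, H, C))
    for (ch in seq_len(C)) out[, , ch] <- t(patch[, , ch])[rev(seq_len(W)), ]
    out
  } else {
    patch[rev(seq_len(H)), rev(seq_len(W)), , drop = FALSE]
  }
}

#' Convert a patch to grayscale
#'
#' Replaces every channel with the luminance mean, so all channels are equal
#' pixelwise afterwards.
#'
#' @param patch H x W x C array.
#' @return grayscale array of the same shape.
#' @export
grayscale_patch <- function(patch) {
  g <- apply(patch, c(1, 2), mean)
  for (ch in seq_len(dim(patch)[3])) patch[, , ch] <- g
  patch
}

# Central zoom-crop to fraction `zoom` of the side, resized back to the
# original size by bilinear interpolation.
zoom_crop_patch <- function(patch, zoom) {
  stopifnot(zoom > 0, zoom <= 1)
  H <- dim(patch)[1]; W <- dim(patch)[2]
  h <- max(2L, round(H * zoom)); w <- max(2L, round(W * zoom))
  r0 <- floor((H - h) / 2); c0 <- floor((W - w) / 2)
  crop <- patch[r0 + seq_len(h), c0 + seq_len(w), , drop = FALSE]
  out <- patch
  for (ch in seq_len(dim(patch)[3]))
    out[, , ch] <- EBImage::resize(crop[, , ch], w = H, h = W)
  pmin(pmax(out, 0), 1)
}

#' Default augmentation plan
#'
#' Probabilities and jitter magnitudes for [apply_augmentation()]. The
#' magnitudes (20 percent jitter, grayscale probability 0.1) are
#' conventional; all are overridable.
#'
#' @param p_hflip,p_vflip flip probabilities.
#' @param p_rotate probability of applying a rotation, drawn uniformly from
#'   `angles`.
#' @param angles allowed rotation angles (subset of 90, 180).
#' @param p_zoom probability of zoom-cropping; zoom factor drawn uniformly
#'   from `zoom_range`.
#' @param zoom_range lower/upper zoom fraction.
#' @param jitter half-width of the multiplicative brightness/contrast/
#'   saturation jitter (default 0.2 means factors in \[0.8, 1.2\]).
#' @param p_grayscale grayscale probability.
#' @return named list, the augmentation plan.
#' @export
augmentation_plan <- function(p_hflip = 0.5, p_vflip = 0.5, p_rotate = 0.5,
                              angles = c(90, 180), p_zoom = 0.5,
                              zoom_range = c(0.8, 1), jitter = 0.2,
                              p_grayscale = 0.1) {
  if (!all(angles %in% c(90, 180)))
    stop("rotation angle must be 90 or 180 degrees")
  list(p_hflip = p_hflip, p_vflip = p_vflip, p_rotate = p_rotate,
       angles = angles, p_zoom = p_zoom, zoom_range = zoom_range,
       jitter = jitter, p_grayscale = p_grayscale)
}

#' Apply the random augmentation pipeline to one patch
#'
#' Draws all randomness from a dedicated stream seeded by `seed`, leaving the
#' caller's RNG untouched: the same `(patch, plan, seed)` triple always
#' produces the same output. Operations are applied in the order flips,
#' rotation, zoom-crop, brightness, contrast, saturation, grayscale; output
#' values are clipped to \[0, 1\].
#'
#' @param patch H x W x C array with values in \[0, 1\].
#' @param plan an [augmentation_plan()].
#' @param seed integer seed for this draw.
#' @return augmented H x W x C array.
#' @export
apply_augmentation <- function(patch, plan = augmentation_plan(), seed = 1) {
  if (min(patch) < 0 || max(patch) > 1)
    stop("`patch` values must lie in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(split_seed(seed, "augmentation"))
  if (stats::runif(1) < plan$p_hflip) patch <- flip_patch(patch, "horizontal")
  if (stats::runif(1) < plan$p_vflip) patch <- flip_patch(patch, "vertical")
  if (stats::runif(1) < plan$p_rotate)
    patch <- rotate_patch(patch, sample(plan$angles, 1))
  if (stats::runif(1) < plan$p_zoom)
    patch <- zoom_crop_patch(patch, stats::runif(1, plan$zoom_range[1],
                                                 plan$zoom_range[2]))
  # brightness: multiplicative gain
  patch <- patch * stats::runif(1, 1 - plan$jitter, 1 + plan$jitter)
  # contrast: scale around the patch mean
  mu <- mean(patch)
  patch <- mu + (patch - mu) * stats::runif(1, 1 - plan$jitter, 1 + plan$jitter)
  # saturation: interpolate between grayscale and the patch
  g <- grayscale_patch(pmin(pmax(patch, 0), 1))
  patch <- g + (patch - g) * stats::runif(1, 1 - plan$jitter, 1 + plan$jitter)
  if (stats::runif(1) < plan$p_grayscale) patch <- grayscale_patch(patch)
  pmin(pmax(patch, 0), 1)
}

#' Resize and standardize a patch
#'
#' Bilinearly resizes to `target_size` x `target_size` and standardizes the
#' whole patch to mean 0 and (population) variance 1, the normalization
#' expected by the classifier. A constant patch cannot be standardized: it
#' returns all zeros with a warning and the attribute `constant_input` set.
#'
#' @param patch H x W x C array.
#' @param target_size output side length (default: input size).
#' @return standardized array (values are no longer confined to \[0, 1\]).
#' @export
normalize_patch <- function(patch, target_size = dim(patch)[1]) {
  C <- dim(patch)[3]
  if (dim(patch)[1] != target_size || dim(patch)[2] != target_size) {
    out <- array(0, dim = c(target_size, target_size, C))
    for (ch in seq_len(C))
      out[, , ch] <- EBImage::resize(patch[, , ch], w = target_size,
                                     h = target_size)
    patch <- out
  }
  mu <- mean(patch)
  s2 <- mean((patch - mu)^2)
  if (s2 <= 0) {
    warning("constant patch cannot be standardized; returning zeros")
    patch[] <- 0
    attr(patch, "constant_input") <- TRUE
    return(patch)
  }
  (patch - mu) / sqrt(s2)
}
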