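#' @title Synthetic histology-texture patches
#' @description The package benchmarks its optimizers on a fully synthetic
#'   stand-in for an eight-class colorectal-tissue patch classification
#'   task. Each class has its own generative recipe -- a smoothed noise
#'   field with a class-specific correlation length, a class-specific count
#'   of Gaussian blobs (dark nuclei-like dots or bright flecks), a base
#'   intensity, and an RGB tint; "EMPTY" is a near-uniform bright patch.
#'   The recipes emulate coarse texture statistics of H&E tissue tiles, not
#'   real stain physics.
#' @name synth-data
NULL

# Deterministic sub-seed for a named random stream, derived from a root seed.
# Keeps every derived seed inside the 32-bit signed range.
split_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 2654435.0 + h * 97.0 + 12345) %% 2147483647)
}

# Full-strength per-class texture recipes (at separability 1). Columns:
# smooth  - box-blur passes (correlation length of the noise field)
# noise   - noise field amplitude
# blobs   - expected blob count
# blob_amp- blob amplitude (negative = dark nuclei-like dots)
# blob_sd - blob radius in pixels (at size 32; scaled with patch size)
# base    - mean intensity
# tint_*  - RGB channel multipliers
class_recipes <- function() {
  data.frame(
    class = crc_class_names(),
    smooth  = c(1,    3,    2,    1,    1,    4,    2,    5),
    noise   = c(0.18, 0.10, 0.14, 0.12, 0.30, 0.08, 0.05, 0.01),
    blobs   = c(25,   3,    12,   30,   8,    5,    6,    0),
    blob_amp= c(-0.35, -0.10, -0.20, -0.45, 0.25, -0.15, -0.30, 0),
    blob_sd = c(1.2,  2.5,  1.8,  1.0,  1.5,  3.0,  3.5,  1.0),
    base    = c(0.45, 0.60, 0.55, 0.50, 0.50, 0.65, 0.85, 0.95),
    tint_r  = c(0.60, 0.90, 0.75, 0.45, 0.65, 0.80, 0.97, 0.98),
    tint_g  = c(0.35, 0.55, 0.50, 0.45, 0.55, 0.60, 0.90, 0.97),
    tint_b  = c(0.65, 0.65, 0.70, 0.80, 0.50, 0.85, 0.93, 0.96),
    stringsAsFactors = FALSE)
}

# Separable box blur with reflecting edges, `passes` times.
box_blur <- function(m, passes) {
  if (passes < 1) return(m)
  n <- nrow(m)
  for (i in seq_len(passes)) {
    up <- m[c(1, seq_len(n - 1)), ]
    dn <- m[c(seq_len(n - 1) + 1, n), ]
    m <- (up + m + dn) / 3
    lf <- m[, c(1, seq_len(n - 1))]
    rt <- m[, c(seq_len(n - 1) + 1, n)]
    m <- (lf + m + rt) / 3
  }
  m
}

# One single-channel texture field for a recipe row (values roughly centred
# on 0; tint/base applied by the caller).
texture_field <- function(size, rec) {
  f <- matrix(stats::rnorm(size * size, 0, 1), size, size)
  f <- box_blur(f, round(rec$smooth))
  f <- f / max(stats::sd(f), 1e-12) * rec$noise
  n_blob <- stats::rpois(1, rec$blobs)
  if (n_blob > 0) {
    xs <- seq_len(size)
    sd_px <- rec$blob_sd * size / 32
    cx <- stats::runif(n_blob, 1, size)
    cy <- stats::runif(n_blob, 1, size)
    for (b in seq_len(n_blob)) {
      d2 <- outer((xs - cy[b])^2, (xs - cx[b])^2, "+")
      f <- f + rec$blob_amp * exp(-d2 / (2 * sd_px^2))
    }
  }
  f
}

#' Generate a synthetic eight-class texture-patch dataset
#'
#' Produces `n_per_class` patches for each of the eight tissue classes, all
#' `size x size x 3` with pixel values in \[0, 1\]. `separability` linearly
#' interpolates every class recipe between the all-class mean recipe (0,
#' classes indistinguishable in expectation) and the full-strength recipes
#' (1); it is the single difficulty dial of the benchmark. Generation is a
#' pure function of `(n_per_class, size, seed, separability)`: the same
#' arguments reproduce the dataset bitwise.
#'
#' @param n_per_class patches per class (>= 1).
#' @param size patch side length in pixels (>= 8; default 32 for desk-scale
#'   runtime -- real tiles are an order of magnitude larger, which only
#'   scales cost, not structure).
#' @param seed integer root seed.
#' @param separability difficulty dial in (0, 1\].
#' @return an object of class `patch_dataset`: list with `patches`
#'   (n x size x size x 3 array), `labels` (integer in 0..7), `class_names`,
#'   `gen_params`, `seed`.
#' @export
make_texture_dataset <- function(n_per_class, size = 32, seed = 1,
                                 separability = 1.0) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1")
  if (size < 8) stop("`size` must be >= 8")
  if (separability <= 0 || separability > 1)
    stop("`separability` must lie in (0, 1]")
  recipes <- class_recipes()
  num <- names(recipes)[-1]
  centre <- colMeans(recipes[num])
  for (cn in num)
    recipes[[cn]] <- centre[[cn]] + separability * (recipes[[cn]] - centre[[cn]])
  K <- nrow(recipes)
  n <- n_per_class * K
  patches <- array(0, dim = c(n, size, size, 3))
  labels <- rep(seq_len(K) - 1L, each = n_per_class)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(split_seed(seed, "dataset"))
  idx <- 0L
  for (k in seq_len(K)) {
    rec <- recipes[k, ]
    tint <- c(rec$tint_r, rec$tint_g, rec$tint_b)
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      f <- texture_field(size, rec)
      for (ch in 1:3)
        patches[idx, , , ch] <- pmin(pmax(rec$base * tint[ch] +
                                            f * tint[ch], 0), 1)
    }
  }
  structure(list(patches = patches, labels = labels,
                 class_names = recipes$class,
                 gen_params = list(n_per_class = n_per_class, size = size,
                                   separability = separability,
                                   recipes = recipes),
                 seed = seed),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  d <- dim(x$patches)
  cat(sprintf("<patch_dataset> %d patches (%dx%dx%d), %d classes, seed %d\n",
              d[1], d[2], d[3], d[4], length(x$class_names), x$seed))
  print(table(x$class_names[x$labels + 1]))
  invisible(x)
}

# Save/restore the global RNG state so generators are pure functions of
# their seed and leave the caller's stream untouched.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Nearest-class-mean oracle accuracy
#'
#' A deliberately simple reference classifier used to calibrate dataset
#' difficulty: class means are computed on a training split of flattened
#' pixels and held-out patches are assigned to the nearest mean (Euclidean).
#'
#' @param data a [make_texture_dataset()] object.
#' @param train_frac fraction of each class used for the means (default 0.5).
#' @return held-out accuracy in \[0, 1\].
#' @export
nearest_mean_accuracy <- function(data, train_frac = 0.5) {
  stopifnot(inherits(data, "patch_dataset"))
  n <- dim(data$patches)[1]
  X <- matrix(data$patches, nrow = n)
  y <- data$labels
  tr <- unlist(lapply(split(seq_len(n), y), function(ix)
    ix[seq_len(max(1, floor(length(ix) * train_frac)))]))
  te <- setdiff(seq_len(n), tr)
  ks <- sort(unique(y))
  means <- t(vapply(ks, function(k) colMeans(X[tr[y[tr] == k], , drop = FALSE]),
                    numeric(ncol(X))))
  d2 <- outer(rowSums(X[te, , drop = FALSE]^2), rowSums(means^2), "+") -
    2 * X[te, , drop = FALSE] %*% t(means)
  pred <- ks[max.col(-d2, ties.method = "first")]
  mean(pred == y[te])
}
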