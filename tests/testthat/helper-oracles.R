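# Independent reference implementations used as oracles. They deliberately
# avoid the package's code paths: per-class counts come straight from the
# label vectors (no confusion matrix), AUC from exhaustive pair comparison
# (Mann-Whitney with half-credit ties).

oracle_prf <- function(y_true, y_pred, classes) {
  out <- lapply(classes, function(k) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      recall = if (tp + fn > 0) tp / (tp + fn) else 0,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
      support = sum(y_true == k))
  })
  do.call(rbind, out)
}

oracle_auc_pairs <- function(y_binary, scores) {
  sp <- scores[y_binary == 1]
  sn <- scores[y_binary == 0]
  if (length(sp) == 0 || length(sn) == 0) return(NA_real_)
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

random_metric_instance <- function(n, K, seed) {
  set.seed(seed)
  classes <- LETTERS[seq_len(K)]
  y_true <- sample(classes, n, replace = TRUE)
  # ensure every class occurs so supports are positive
  y_true[seq_len(K)] <- classes
  scores <- matrix(rnorm(n * K), n, K)
  # correlate scores with truth so instances are non-trivial
  scores[cbind(seq_len(n), match(y_true, classes))] <-
    scores[cbind(seq_len(n), match(y_true, classes))] + runif(1, 0, 2)
  y_pred <- classes[max.col(scores, ties.method = "first")]
  list(y_true = y_true, y_pred = y_pred, scores = scores, classes = classes)
}

# Central finite-difference gradient of the classifier loss.
fd_gradient <- function(model, X, y, h = 1e-5) {
  grads <- list()
  for (nm in names(model$params$entries)) {
    g <- model$params$entries[[nm]]
    g[] <- 0
    for (i in seq_along(g)) {
      mp <- model; mm <- model
      mp$params$entries[[nm]][i] <- mp$params$entries[[nm]][i] + h
      mm$params$entries[[nm]][i] <- mm$params$entries[[nm]][i] - h
      g[i] <- (loss_and_grad(mp, X, y)$loss -
                 loss_and_grad(mm, X, y)$loss) / (2 * h)
    }
    grads[[nm]] <- g
  }
  grads
}

# Tiny two-entry parameter block used across the optimizer tests.
toy_params <- function(theta = c(0.5, -1, 2), w = matrix(1:4 / 4, 2, 2)) {
  param_block(list(theta = theta, w = w))
}

random_gradient_like <- function(params) {
  lapply(params$entries, function(e) {
    g <- e
    g[] <- rnorm(length(e))
    g
  })
}

# A tiny separable two-class patch dataset (dark vs bright patches) built
# by hand; exercises the training loop without the 8-class generator.
two_class_patches <- function(n_per_class = 100, size = 8, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  patches <- array(0, dim = c(n, size, size, 3))
  labels <- rep(0:1, each = n_per_class)
  for (i in seq_len(n)) {
    # classes differ in channel tint (red- vs blue-dominant), a contrast
    # that survives per-patch standardization
    tint <- if (labels[i] == 0) c(0.7, 0.5, 0.3) else c(0.3, 0.5, 0.7)
    for (ch in 1:3)
      patches[i, , , ch] <- pmin(pmax(tint[ch] +
                                        matrix(rnorm(size * size, 0, 0.1),
                                               size, size), 0), 1)
  }
  structure(list(patches = patches, labels = labels,
                 class_names = c("DARK", "BRIGHT"),
                 gen_params = list(synthetic = TRUE), seed = seed),
            class = "patch_dataset")
}
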