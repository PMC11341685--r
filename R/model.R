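#' Small classifier with explicit forward/backward passes
#'
#' Two architectures over flattened pixel features:
#' * `"softmax"` -- multinomial logistic regression (`head.W`, `head.b`);
#' * `"mlp"` -- one hidden rectifier layer of width `hidden`
#'   (`features.W`, `features.b`) followed by a softmax head -- freezing
#'   the `features.*` entries emulates fine-tuning a pretrained feature
#'   extractor.
#'
#' Weights are initialized uniformly on \eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}}
#' with zero biases, from a dedicated seeded stream.
#'
#' @param n_features input dimension (flattened pixels).
#' @param n_classes number of classes K.
#' @param arch `"softmax"` or `"mlp"`.
#' @param hidden hidden width for `"mlp"` (default 32).
#' @param seed integer init seed.
#' @return an object of class `classifier_model` with fields `params`
#'   (a [param_block()]), `arch`, `n_features`, `n_classes`, `hidden`,
#'   `seed`.
#' @export
init_classifier <- function(n_features, n_classes, arch = c("softmax", "mlp"),
                            hidden = 32L, seed = 1) {
  arch <- match.arg(arch)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(split_seed(seed, "init"))
  glorot <- function(fin, fout)
    matrix(stats::runif(fin * fout, -1, 1) * sqrt(6 / (fin + fout)), fin, fout)
  entries <- if (arch == "softmax") {
    list(head.W = glorot(n_features, n_classes),
         head.b = numeric(n_classes))
  } else {
    list(features.W = glorot(n_features, hidden),
         features.b = numeric(hidden),
         head.W = glorot(hidden, n_classes),
         head.b = numeric(n_classes))
  }
  structure(list(params = param_block(entries), arch = arch,
                 n_features = n_features, n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden), seed = seed),
            class = "classifier_model")
}

# Row-wise numerically stable softmax.
row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Forward pass: class probabilities
#'
#' @param model a [init_classifier()] model.
#' @param X n x d feature matrix.
#' @return n x K matrix of probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "classifier_model"))
  X <- as.matrix(X)
  p <- model$params$entries
  if (model$arch == "softmax") {
    Z <- X %*% p$head.W + matrix(p$head.b, nrow(X), model$n_classes,
                                 byrow = TRUE)
  } else {
    H <- pmax(X %*% p$features.W +
                matrix(p$features.b, nrow(X), model$hidden, byrow = TRUE), 0)
    Z <- H %*% p$head.W + matrix(p$head.b, nrow(X), model$n_classes,
                                 byrow = TRUE)
  }
  row_softmax(Z)
}

#' Cross-entropy loss and analytic gradient
#'
#' Mean multinomial cross-entropy over the batch. The returned gradient is
#' the pure data term; the training loop adds the coupled L2 contribution
#' from [l2_penalty_and_grad()] before the optimizer step, so the optimized
#' objective is \eqn{CE + \lambda\sum\|w\|^2}.
#'
#' @param model a `classifier_model`.
#' @param X n x d batch.
#' @param y integer labels in `0..K-1`.
#' @return list with `loss` (scalar) and `grad` (named list shape-matched to
#'   the model's parameters).
#' @export
loss_and_grad <- function(model, X, y) {
  stopifnot(inherits(model, "classifier_model"))
  X <- as.matrix(X)
  n <- nrow(X)
  K <- model$n_classes
  stopifnot(length(y) == n, all(y >= 0 & y < K))
  p <- model$params$entries
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  if (model$arch == "softmax") {
    Z <- X %*% p$head.W + matrix(p$head.b, n, K, byrow = TRUE)
    P <- row_softmax(Z)
    dZ <- (P - Y) / n
    grad <- list(head.W = t(X) %*% dZ, head.b = colSums(dZ))
  } else {
    A <- X %*% p$features.W + matrix(p$features.b, n, model$hidden,
                                     byrow = TRUE)
    H <- pmax(A, 0)
    Z <- H %*% p$head.W + matrix(p$head.b, n, K, byrow = TRUE)
    P <- row_softmax(Z)
    dZ <- (P - Y) / n
    dH <- (dZ %*% t(p$head.W)) * (A > 0)
    grad <- list(features.W = t(X) %*% dH, features.b = colSums(dH),
                 head.W = t(H) %*% dZ, head.b = colSums(dZ))
  }
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-300)))
  list(loss = loss, grad = grad)
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("<classifier_model> %s, %d features -> %d classes%s\n",
              x$arch, x$n_features, x$n_classes,
              if (x$arch == "mlp") sprintf(" (hidden %d)", x$hidden) else ""))
  invisible(x)
}

#' Serialize / restore a classifier model
#'
#' @param model a `classifier_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_classifier_json()` returns the model.
#' @export
write_classifier_json <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  ent <- lapply(model$params$entries, function(e)
    list(dim = if (is.null(dim(e))) length(e) else dim(e), data = as.numeric(e)))
  jsonlite::write_json(list(arch = model$arch, n_features = model$n_features,
                            n_classes = model$n_classes, hidden = model$hidden,
                            seed = model$seed,
                            frozen = model$params$frozen, entries = ent),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(j$entries, function(e) {
    v <- as.numeric(e$data)
    if (length(e$dim) > 1) array(v, dim = as.integer(e$dim)) else v
  })
  pb <- param_block(entries, frozen = as.character(unlist(j$frozen)))
  structure(list(params = pb, arch = j$arch, n_features = j$n_features,
                 n_classes = as.integer(j$n_classes),
                 hidden = as.integer(j$hidden), seed = j$seed),
            class = "classifier_model")
}
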