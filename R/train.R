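#' Training configuration
#'
#' @param optimizer one of `"sgd"`, `"adagrad"`, `"adam"`, `"sadagrad"`.
#' @param epochs number of passes over the training split (>= 0).
#' @param batch_size minibatch size (default 64).
#' @param hp [hyper_params()]; defaults to the optimizer's conventional
#'   defaults. `hp$lambda_wd > 0` turns on coupled L2 weight decay.
#' @param sched SAdagrad's [build_schedule()]; ignored by the other
#'   optimizers.
#' @param arch,hidden classifier architecture, see [init_classifier()].
#' @param frozen character vector of parameter entries to freeze.
#' @param augment logical: apply the random augmentation pipeline to every
#'   training patch each epoch.
#' @param plan [augmentation_plan()] used when `augment = TRUE`.
#' @param seed integer seed controlling init, shuffling and augmentation
#'   (each on its own derived stream).
#' @return an object of class `train_config`.
#' @export
train_config <- function(optimizer = "sadagrad", epochs = 30L,
                         batch_size = 64L,
                         hp = default_hyperparams(optimizer),
                         sched = build_schedule(horizon = max(epochs, 1)),
                         arch = "softmax", hidden = 32L,
                         frozen = character(), augment = FALSE,
                         plan = augmentation_plan(), seed = 1) {
  if (!optimizer %in% c("sgd", "adagrad", "adam", "sadagrad"))
    stop("unknown optimizer '", optimizer,
         "'; choices: sgd, adagrad, adam, sadagrad")
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  if (epochs < 0) stop("`epochs` must be >= 0")
  if (batch_size < 1) stop("`batch_size` must be >= 1")
  structure(list(optimizer = optimizer, epochs = epochs,
                 batch_size = batch_size, hp = hp, sched = sched,
                 arch = arch, hidden = as.integer(hidden), frozen = frozen,
                 augment = isTRUE(augment), plan = plan, seed = seed),
            class = "train_config")
}

# Deterministic 70/30 stratified split keyed to the dataset seed, so every
# configuration trained on the same dataset shares the same held-out set.
split_dataset <- function(data, train_frac = 0.7) {
  stopifnot(inherits(data, "patch_dataset"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(split_seed(data$seed, "split"))
  n <- dim(data$patches)[1]
  train <- unlist(lapply(split(seq_len(n), data$labels), function(ix) {
    k <- max(1L, round(length(ix) * train_frac))
    sample(ix, k)
  }), use.names = FALSE)
  list(train = sort(train), test = setdiff(seq_len(n), train))
}

# Flatten patches to an n x d feature matrix, standardizing each patch.
flatten_patches <- function(patches) {
  n <- dim(patches)[1]
  X <- matrix(patches, nrow = n)
  mu <- rowMeans(X)
  sd_pop <- sqrt(rowMeans((X - mu)^2))
  sd_pop[sd_pop <= 0] <- 1
  (X - mu) / sd_pop
}

# One optimizer step dispatched by name; returns list(params, state).
dispatch_step <- function(optimizer, params, grad, state, sched, hp) {
  switch(optimizer,
    sgd = list(params = sgd_step(params, grad, hp), state = state),
    adagrad = adagrad_step(params, grad, state, hp)[c("params", "state")],
    adam = adam_step(params, grad, state, hp)[c("params", "state")],
    sadagrad = sadagrad_step(params, grad, state, sched, hp)[c("params",
                                                               "state")])
}

#' Train a classifier on a patch dataset
#'
#' Minibatch training of the toy classifier under any of the four
#' optimizers, on a fixed 70/30 stratified split keyed to the dataset seed.
#' The optimized objective is mean cross-entropy plus, when
#' `cfg$hp$lambda_wd > 0`, the coupled L2 penalty (its gradient is added to
#' the loss gradient before every step). Epoch-wise reshuffling, weight
#' initialization, and augmentation draw from separate streams derived from
#' `cfg$seed`, so two runs with identical configuration and seed produce
#' bitwise-identical parameters. SAdagrad's epoch counter advances once per
#' pass, selecting the scheduled base rate.
#'
#' @param data a [make_texture_dataset()] dataset (or any `patch_dataset`).
#' @param cfg a [train_config()].
#' @return list with `model` (final `classifier_model`) and `result`
#'   (class `run_result`): per-epoch `train_loss` and `train_accuracy`,
#'   the per-epoch scheduled rate `ls` (SAdagrad only), the held-out
#'   `report` (aggregated `class_report`), per-class `auc`, and
#'   `test_accuracy`.
#' @export
train_classifier <- function(data, cfg) {
  stopifnot(inherits(data, "patch_dataset"), inherits(cfg, "train_config"))
  n <- dim(data$patches)[1]
  if (n == 0) stop("`data` is empty")
  K <- length(data$class_names)
  sp <- split_dataset(data)
  X_all <- flatten_patches(data$patches)
  y <- data$labels
  model <- init_classifier(ncol(X_all), K, arch = cfg$arch,
                           hidden = cfg$hidden, seed = cfg$seed)
  model$params <- set_frozen(model$params, cfg$frozen)
  state <- switch(cfg$optimizer,
                  adagrad = adagrad_state_init(model$params),
                  adam = adam_state_init(model$params),
                  sadagrad = sadagrad_state_init(model$params),
                  NULL)
  train_loss <- numeric(cfg$epochs)
  train_acc <- numeric(cfg$epochs)
  ls_trace <- numeric(cfg$epochs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (e in seq_len(cfg$epochs)) {
    set.seed(split_seed(cfg$seed + 7919 * (e - 1L), "batching"))
    order_e <- sample(sp$train)
    if (cfg$optimizer == "sadagrad") {
      state$epoch <- e - 1L
      ls_trace[e] <- rate_at_epoch(cfg$sched, e - 1L)
    }
    Xe <- X_all[order_e, , drop = FALSE]
    if (cfg$augment) {
      aug <- data$patches[order_e, , , , drop = FALSE]
      for (i in seq_along(order_e)) {
        a <- apply_augmentation(aug[i, , , ], cfg$plan,
                                seed = split_seed(cfg$seed, "augment") +
                                  (e - 1L) * length(order_e) + i)
        Xe[i, ] <- as.numeric(normalize_patch(a))
      }
    }
    ye <- y[order_e]
    batches <- split(seq_along(order_e),
                     ceiling(seq_along(order_e) / cfg$batch_size))
    losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      ix <- batches[[b]]
      lg <- loss_and_grad(model, Xe[ix, , drop = FALSE], ye[ix])
      loss_b <- lg$loss
      grad <- lg$grad
      if (cfg$hp$lambda_wd > 0) {
        wd <- l2_penalty_and_grad(model$params, cfg$hp$lambda_wd)
        loss_b <- loss_b + wd$penalty
        grad <- add_gradients(grad, wd$grad_contrib)
      }
      st <- dispatch_step(cfg$optimizer, model$params, grad, state,
                          cfg$sched, cfg$hp)
      model$params <- st$params
      state <- st$state
      losses[b] <- loss_b
    }
    train_loss[e] <- mean(losses)
    P <- predict_proba(model, X_all[sp$train, , drop = FALSE])
    train_acc[e] <- mean(max.col(P, ties.method = "first") - 1L ==
                           y[sp$train])
  }
  eval_out <- evaluate_model(model, data, indices = sp$test)
  result <- structure(list(train_loss = train_loss,
                           train_accuracy = train_acc,
                           ls = if (cfg$optimizer == "sadagrad") ls_trace
                                else NULL,
                           report = eval_out$report, auc = eval_out$auc,
                           test_accuracy = eval_out$accuracy,
                           optimizer = cfg$optimizer, seed = cfg$seed),
                      class = "run_result")
  list(model = model, result = result)
}

#' Evaluate a classifier on a patch dataset
#'
#' Argmax predictions (ties broken toward the lower class index) feed the
#' confusion matrix and per-class/aggregate precision-recall-F1; the
#' probability columns feed the one-vs-rest AUC.
#'
#' @param model a `classifier_model`.
#' @param data a `patch_dataset` whose class count matches the model.
#' @param indices optional row indices to evaluate (default: all patches).
#' @return list with `report` (aggregated `class_report`), `auc` (named
#'   per-class vector), `accuracy`, `predictions`, `probabilities`.
#' @export
evaluate_model <- function(model, data, indices = NULL) {
  stopifnot(inherits(model, "classifier_model"),
            inherits(data, "patch_dataset"))
  K <- length(data$class_names)
  if (K != model$n_classes)
    stop("model expects ", model$n_classes, " classes but data has ", K)
  if (is.null(indices)) indices <- seq_len(dim(data$patches)[1])
  X <- flatten_patches(data$patches[indices, , , , drop = FALSE])
  y <- data$labels[indices]
  P <- predict_proba(model, X)
  pred <- max.col(P, ties.method = "first") - 1L
  cn <- data$class_names
  cm <- confusion_matrix(cn[y + 1L], cn[pred + 1L], cn)
  report <- aggregate_prf(per_class_prf(cm))
  auc <- auc_ovr(cn[y + 1L], P, cn)
  list(report = report, auc = auc, accuracy = mean(pred == y),
       predictions = pred, probabilities = P)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s, %d epochs, final train acc %.3f, test acc %.3f\n",
              x$optimizer, length(x$train_loss),
              if (length(x$train_accuracy)) utils::tail(x$train_accuracy, 1)
              else NA_real_, x$test_accuracy))
  invisible(x)
}

#' Benchmark the adaptive optimizers on one dataset
#'
#' Runs Adagrad, Adam and SAdagrad from identical initialization for each
#' seed and summarizes median final held-out accuracy per optimizer,
#' mirroring a three-optimizer comparison design. As a wired self-check, the
#' first seed is additionally run with a constant (zero-decay, zero-floor)
#' SAdagrad schedule, whose loss curve must be identical to Adagrad's to the
#' last bit.
#'
#' @param data a `patch_dataset`.
#' @param base_cfg a [train_config()] providing epochs, batch size, arch and
#'   hyperparameter template (its optimizer field is ignored).
#' @param seeds integer vector of run seeds (>= 1 seed).
#' @return an object of class `benchmark_result`: list with `summary`
#'   (data frame of per-optimizer median final accuracy), `runs` (nested
#'   list of `run_result` by optimizer and seed), and `self_check`
#'   (logical: constant-schedule SAdagrad reproduced Adagrad bit-for-bit).
#' @export
benchmark_optimizers <- function(data, base_cfg, seeds = 1:5) {
  stopifnot(inherits(data, "patch_dataset"), inherits(base_cfg, "train_config"))
  if (length(seeds) < 1) stop("at least one seed is required")
  optimizers <- c("adagrad", "adam", "sadagrad")
  runs <- stats::setNames(vector("list", length(optimizers)), optimizers)
  for (opt in optimizers) {
    runs[[opt]] <- lapply(seeds, function(s) {
      cfg <- base_cfg
      cfg$optimizer <- opt
      cfg$hp <- default_hyperparams(opt)
      cfg$hp$lambda_wd <- base_cfg$hp$lambda_wd
      cfg$seed <- s
      train_classifier(data, cfg)$result
    })
  }
  const_cfg <- base_cfg
  const_cfg$optimizer <- "sadagrad"
  const_cfg$hp <- default_hyperparams("sadagrad")
  const_cfg$hp$lambda_wd <- base_cfg$hp$lambda_wd
  const_cfg$seed <- seeds[1]
  const_cfg$sched <- build_schedule(eta0 = default_hyperparams("adagrad")$eta,
                                    decay = 0, floor = 0,
                                    horizon = max(base_cfg$epochs, 1))
  const_run <- train_classifier(data, const_cfg)$result
  self_check <- identical(const_run$train_loss,
                          runs[["adagrad"]][[1]]$train_loss)
  acc <- function(opt) vapply(runs[[opt]], function(r) r$test_accuracy, 1)
  summary <- data.frame(
    optimizer = optimizers,
    median_accuracy = vapply(optimizers, function(o) stats::median(acc(o)), 1),
    min_accuracy = vapply(optimizers, function(o) min(acc(o)), 1),
    max_accuracy = vapply(optimizers, function(o) max(acc(o)), 1),
    row.names = NULL)
  structure(list(summary = summary, runs = runs, self_check = self_check,
                 seeds = seeds),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> seeds:", paste(x$seeds, collapse = ", "),
      "| constant-schedule self-check:",
      if (x$self_check) "passed" else "FAILED", "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
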