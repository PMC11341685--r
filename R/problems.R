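#' @title Convex test problems
#' @description Small convex objectives with analytically known gradients
#'   (and, where one exists, a known minimizer) used as the verification
#'   substrate for the optimizer update rules.
#' @name convex-problems
NULL

new_convex_problem <- function(objective, minimizer, name) {
  structure(list(objective = objective, minimizer = minimizer, name = name),
            class = "convex_problem")
}

#' @export
print.convex_problem <- function(x, ...) {
  cat("<convex_problem> ", x$name,
      if (is.null(x$minimizer)) " (no finite minimizer)" else
        paste0(", dim ", length(x$minimizer)), "\n", sep = "")
  invisible(x)
}

#' Random positive-definite quadratic
#'
#' \eqn{f(\theta) = \tfrac12 (\theta-\theta^*)^\top A (\theta-\theta^*)} with
#' \eqn{A = Q D Q^\top}, eigenvalues spaced geometrically from 1 to
#' `condition_number`, random orthogonal \eqn{Q} and random \eqn{\theta^*}.
#' In one dimension this is \eqn{\tfrac12 a (\theta-\theta^*)^2}.
#'
#' @param dim problem dimension (>= 1).
#' @param condition_number ratio of extreme curvatures (>= 1).
#' @param seed integer seed.
#' @param minimizer optional fixed \eqn{\theta^*} (length `dim`); random by
#'   default.
#' @return a `convex_problem`; `objective(theta)` returns
#'   `list(value, gradient)`.
#' @export
make_quadratic_problem <- function(dim = 1, condition_number = 1, seed = 1,
                                   minimizer = NULL) {
  if (dim < 1) stop("`dim` must be >= 1")
  if (condition_number < 1) stop("`condition_number` must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(split_seed(seed, "quadratic"))
  ev <- if (dim == 1) 1 else exp(seq(0, log(condition_number), length.out = dim))
  Q <- qr.Q(qr(matrix(stats::rnorm(dim * dim), dim, dim)))
  A <- Q %*% (ev * t(Q))
  A <- (A + t(A)) / 2
  theta_star <- if (is.null(minimizer)) stats::rnorm(dim, 0, 2) else
    as.numeric(minimizer)
  stopifnot(length(theta_star) == dim)
  new_convex_problem(
    objective = function(theta) {
      d <- as.numeric(theta) - theta_star
      list(value = 0.5 * sum(d * (A %*% d)), gradient = as.numeric(A %*% d))
    },
    minimizer = theta_star,
    name = sprintf("quadratic(dim=%d, cond=%g)", dim, condition_number))
}

# Logistic loss helpers: numerically stable log(1 + exp(z)).
log1pexp <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))

#' Separable logistic-regression problem
#'
#' Draws `n` Gaussian feature vectors, labels them by a planted unit weight
#' vector, and pushes every point outward so that the signed margin
#' \eqn{y_i\, x_i^\top w^*} is at least `margin`. The objective over weights
#' is mean logistic cross-entropy plus, when `lambda > 0`, the coupled L2
#' penalty \eqn{\lambda \|w\|^2} (wired through [l2_penalty_and_grad()]).
#' With `lambda = 0` the separable problem has no finite minimizer and the
#' `minimizer` field is `NULL`; with `lambda > 0` the unique minimizer is
#' computed at construction (BFGS then Newton polish to gradient norm below
#' 1e-10).
#'
#' @param n number of samples (>= 2).
#' @param dim feature dimension.
#' @param margin positive worst-case margin at the planted weights.
#' @param seed integer seed.
#' @param lambda non-negative L2 coefficient.
#' @return list with `features` (n x dim), `labels` (+-1), `planted_w` (the
#'   separating unit vector), and `problem` (a `convex_problem` over
#'   weights).
#' @export
make_logreg_problem <- function(n, dim = 2, margin = 0.5, seed = 1,
                                lambda = 0) {
  if (n < 2) stop("`n` must be >= 2")
  if (margin <= 0) stop("`margin` must be positive")
  if (lambda < 0) stop("`lambda` must be non-negative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(split_seed(seed, "logreg"))
  w_star <- stats::rnorm(dim)
  w_star <- w_star / sqrt(sum(w_star^2))
  X <- matrix(stats::rnorm(n * dim), n, dim)
  y <- as.numeric(ifelse(X %*% w_star >= 0, 1, -1))
  # guarantee both labels occur
  if (all(y == y[1])) y[1] <- -y[1]
  m <- as.numeric(X %*% w_star) * y
  short <- m < margin
  X[short, ] <- X[short, ] + (margin - m[short]) * y[short] %o% w_star
  objective <- function(w) {
    w <- as.numeric(w)
    z <- -y * as.numeric(X %*% w)
    value <- mean(log1pexp(z)) + lambda * sum(w^2)
    p <- 1 / (1 + exp(-z)) # sigmoid(-y x w)
    grad <- -as.numeric(t(X) %*% (y * p)) / n + 2 * lambda * w
    list(value = value, gradient = grad)
  }
  minimizer <- NULL
  if (lambda > 0) {
    opt <- stats::optim(rep(0, dim), fn = function(w) objective(w)$value,
                        gr = function(w) objective(w)$gradient,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    w <- opt$par
    for (i in 1:50) { # Newton polish to machine precision
      z <- -y * as.numeric(X %*% w)
      p <- 1 / (1 + exp(-z))
      g <- -as.numeric(t(X) %*% (y * p)) / n + 2 * lambda * w
      if (sqrt(sum(g^2)) < 1e-12) break
      s <- p * (1 - p)
      H <- t(X) %*% (X * s) / n + diag(2 * lambda, dim)
      w <- w - solve(H, g)
    }
    minimizer <- w
  }
  list(features = X, labels = y, planted_w = w_star,
       problem = new_convex_problem(objective, minimizer,
                                    sprintf("logreg(n=%d, dim=%d, margin=%g, lambda=%g)",
                                            n, dim, margin, lambda)))
}

#' Run an optimizer on a convex problem
#'
#' Full-batch loop over a `convex_problem`; for SAdagrad one step counts as
#' one epoch of the schedule (each step sees the entire objective).
#'
#' @param problem a `convex_problem`.
#' @param optimizer one of `"sgd"`, `"adagrad"`, `"adam"`, `"sadagrad"`.
#' @param theta0 starting point.
#' @param steps maximum number of steps.
#' @param hp [hyper_params()]; defaults to the optimizer's conventional
#'   defaults.
#' @param sched schedule for SAdagrad (default [build_schedule()] with a
#'   horizon covering `steps`).
#' @param tol if non-`NULL`, stop as soon as
#'   \eqn{\|\theta-\theta^*\|_\infty < tol} (requires a known minimizer).
#' @return list with `theta` (final), `steps_taken`, `converged`, and the
#'   `loss` trace.
#' @export
optimize_problem <- function(problem, optimizer, theta0, steps,
                             hp = default_hyperparams(optimizer),
                             sched = build_schedule(horizon = max(steps, 1)),
                             tol = NULL) {
  stopifnot(inherits(problem, "convex_problem"))
  optimizer <- match.arg(optimizer, c("sgd", "adagrad", "adam", "sadagrad"))
  params <- param_block(list(theta = as.numeric(theta0)))
  state <- switch(optimizer,
                  adagrad = adagrad_state_init(params),
                  adam = adam_state_init(params),
                  sadagrad = sadagrad_state_init(params),
                  NULL)
  loss <- numeric(0)
  converged <- FALSE
  taken <- 0L
  for (t in seq_len(steps)) {
    ev <- problem$objective(params$entries$theta)
    loss[t] <- ev$value
    g <- list(theta = ev$gradient)
    if (optimizer == "sgd") {
      params <- sgd_step(params, g, hp)
    } else if (optimizer == "adagrad") {
      st <- adagrad_step(params, g, state, hp)
      params <- st$params; state <- st$state
    } else if (optimizer == "adam") {
      st <- adam_step(params, g, state, hp)
      params <- st$params; state <- st$state
    } else {
      st <- sadagrad_step(params, g, state, sched, hp)
      params <- st$params
      state <- sadagrad_advance_epoch(st$state)
    }
    taken <- t
    if (!is.null(tol) && !is.null(problem$minimizer) &&
        max(abs(params$entries$theta - problem$minimizer)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(theta = params$entries$theta, steps_taken = taken,
       converged = converged, loss = loss)
}
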