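#' @title Optimizer update rules
#' @description From-scratch implementations of the four update rules. All of
#'   them share the same contract: they take a [param_block()], a gradient
#'   (named list shape-matched to the parameters), per-algorithm persistent
#'   state, and [hyper_params()], and return the updated parameters plus
#'   state. Frozen entries and their state slots are never touched.
#' @name optim-steps
NULL

#' Fresh Adagrad state
#'
#' The accumulator holds the per-coordinate running sum of squared gradients;
#' it starts at zero and is non-decreasing for the life of the run. Adagrad's
#' effective per-coordinate rate is \eqn{\eta/\sqrt{s_t + \epsilon}}, which
#' therefore decays monotonically -- the very behaviour SAdagrad mitigates.
#'
#' @param params the [param_block()] the state will track.
#' @return an object of class `adagrad_state`.
#' @export
adagrad_state_init <- function(params) {
  stopifnot(inherits(params, "param_block"))
  structure(list(accumulator = zeros_like(params)), class = "adagrad_state")
}

#' Fresh Adam state
#'
#' First and second moment estimates start at zero with the step counter at
#' t = 0; bias correction divides by \eqn{1-\beta^t} so that at t = 1 the
#' corrected first moment equals the gradient exactly.
#'
#' @inheritParams adagrad_state_init
#' @return an object of class `adam_state` with fields `m`, `v`, `t`.
#' @export
adam_state_init <- function(params) {
  stopifnot(inherits(params, "param_block"))
  structure(list(m = zeros_like(params), v = zeros_like(params), t = 0L),
            class = "adam_state")
}

#' Fresh SAdagrad state
#'
#' Same squared-gradient history as Adagrad plus the current epoch index,
#' which selects the base rate from the learning-rate table.
#'
#' @inheritParams adagrad_state_init
#' @param epoch starting epoch index (>= 0).
#' @return an object of class `sadagrad_state`.
#' @export
sadagrad_state_init <- function(params, epoch = 0L) {
  stopifnot(inherits(params, "param_block"), epoch >= 0)
  structure(list(accumulator = zeros_like(params), epoch = as.integer(epoch)),
            class = "sadagrad_state")
}

#' Plain stochastic gradient descent step
#'
#' \eqn{\theta' = \theta - \eta g} on every unfrozen entry; the fixed global
#' rate is what the adaptive methods improve upon.
#'
#' @param params a [param_block()].
#' @param grad named list of gradient arrays shape-matched to `params`.
#' @param hp a [hyper_params()] object.
#' @return the updated `param_block`.
#' @export
sgd_step <- function(params, grad, hp = default_hyperparams("sgd")) {
  stopifnot(inherits(params, "param_block"), inherits(hp, "hyper_params"))
  check_gradient(params, grad)
  for (nm in active_names(params)) {
    params$entries[[nm]] <- params$entries[[nm]] - hp$eta * grad[[nm]]
  }
  params
}

#' Adagrad step
#'
#' Accumulates squared gradients and scales each coordinate's step by the
#' inverse square root of its history:
#' \deqn{s' = s + g \odot g, \qquad
#'       \theta' = \theta - \frac{\eta}{\sqrt{s' + \epsilon}} \odot g.}
#' The guard \eqn{\epsilon} sits inside the square root. The effective
#' per-coordinate rate \eqn{\eta/\sqrt{s'+\epsilon}} is returned in the step
#' metadata so callers can observe the decay.
#'
#' @inheritParams sgd_step
#' @param state an [adagrad_state_init()] object.
#' @return list with elements `params`, `state`, and `meta` (containing
#'   `effective_rate`, the per-coordinate rates actually applied).
#' @export
adagrad_step <- function(params, grad, state,
                         hp = default_hyperparams("adagrad")) {
  stopifnot(inherits(params, "param_block"), inherits(state, "adagrad_state"),
            inherits(hp, "hyper_params"))
  check_gradient(params, grad)
  rates <- list()
  for (nm in active_names(params)) {
    g <- grad[[nm]]
    state$accumulator[[nm]] <- state$accumulator[[nm]] + g * g
    r <- hp$eta / sqrt(state$accumulator[[nm]] + hp$epsilon)
    params$entries[[nm]] <- params$entries[[nm]] - r * g
    rates[[nm]] <- r
  }
  list(params = params, state = state,
       meta = list(effective_rate = rates))
}

#' Adam step
#'
#' Exponential moving averages of the gradient and its square, bias-corrected
#' for their zero initialization:
#' \deqn{m' = \beta_1 m + (1-\beta_1) g, \quad
#'       v' = \beta_2 v + (1-\beta_2) g \odot g,}
#' \deqn{\hat m = m'/(1-\beta_1^{t'}), \quad \hat v = v'/(1-\beta_2^{t'}),
#'       \quad \theta' = \theta - \eta\, \hat m / (\sqrt{\hat v} + \epsilon)}
#' with \eqn{t' = t + 1}. Both moments are corrected and \eqn{\epsilon} sits
#' outside the square root (standard Adam).
#'
#' @inheritParams sgd_step
#' @param state an [adam_state_init()] object.
#' @return list with elements `params`, `state`, `meta` (with `m_hat`,
#'   `v_hat`).
#' @export
adam_step <- function(params, grad, state, hp = default_hyperparams("adam")) {
  stopifnot(inherits(params, "param_block"), inherits(state, "adam_state"),
            inherits(hp, "hyper_params"))
  check_gradient(params, grad)
  state$t <- state$t + 1L
  c1 <- 1 - hp$beta1^state$t
  c2 <- 1 - hp$beta2^state$t
  m_hat <- list(); v_hat <- list()
  for (nm in active_names(params)) {
    g <- grad[[nm]]
    state$m[[nm]] <- hp$beta1 * state$m[[nm]] + (1 - hp$beta1) * g
    state$v[[nm]] <- hp$beta2 * state$v[[nm]] + (1 - hp$beta2) * g * g
    mh <- state$m[[nm]] / c1
    vh <- state$v[[nm]] / c2
    params$entries[[nm]] <- params$entries[[nm]] -
      hp$eta * mh / (sqrt(vh) + hp$epsilon)
    m_hat[[nm]] <- mh; v_hat[[nm]] <- vh
  }
  list(params = params, state = state,
       meta = list(m_hat = m_hat, v_hat = v_hat))
}

#' SAdagrad step: scheduled Adagrad with a step-size floor
#'
#' Keeps Adagrad's full squared-gradient history but draws the base rate from
#' the per-epoch table LS and clips the effective per-coordinate rate from
#' below:
#' \deqn{s' = s + g \odot g, \qquad
#'       r = \max\!\left(\frac{LS(e)}{\sqrt{s' + \epsilon}},\
#'       \eta_{floor}\right), \qquad \theta' = \theta - r \odot g.}
#' The floor prevents the step size from collapsing as the accumulator grows,
#' which is plain Adagrad's main failure mode on long runs. With `decay = 0`
#' and `floor = 0` the rule reduces bit-for-bit to Adagrad at
#' \eqn{\eta = LS(0)}. Per-step cost stays linear in the parameter count.
#'
#' @inheritParams sgd_step
#' @param state an [sadagrad_state_init()] object; its `epoch` field selects
#'   the schedule entry (advance it with [sadagrad_advance_epoch()]).
#' @param sched a [build_schedule()] object.
#' @return list with elements `params`, `state`, `meta` (with
#'   `effective_rate` and the base rate `ls` used).
#' @export
sadagrad_step <- function(params, grad, state, sched,
                          hp = default_hyperparams("sadagrad")) {
  stopifnot(inherits(params, "param_block"),
            inherits(state, "sadagrad_state"),
            inherits(sched, "lr_schedule"), inherits(hp, "hyper_params"))
  check_gradient(params, grad)
  ls <- rate_at_epoch(sched, state$epoch)
  rates <- list()
  for (nm in active_names(params)) {
    g <- grad[[nm]]
    state$accumulator[[nm]] <- state$accumulator[[nm]] + g * g
    r <- pmax(ls / sqrt(state$accumulator[[nm]] + hp$epsilon), sched$floor)
    params$entries[[nm]] <- params$entries[[nm]] - r * g
    rates[[nm]] <- r
  }
  list(params = params, state = state,
       meta = list(effective_rate = rates, ls = ls))
}

#' Advance the SAdagrad epoch counter
#'
#' @param state an `sadagrad_state`.
#' @param by non-negative integer increment (default 1).
#' @return the updated state (epoch is non-decreasing by construction).
#' @export
sadagrad_advance_epoch <- function(state, by = 1L) {
  stopifnot(inherits(state, "sadagrad_state"), by >= 0)
  state$epoch <- state$epoch + as.integer(by)
  state
}

#' L2 weight-decay penalty and its gradient
#'
#' Coupled weight decay: the penalized objective is
#' \eqn{L(w) + \lambda \sum \|w\|^2}, so the penalty contributes
#' \eqn{2\lambda w} to the gradient of every unfrozen entry. Callers add
#' `grad_contrib` to the loss gradient before any optimizer step; the decay
#' drives weights toward (but not exactly to) zero.
#'
#' @param params a [param_block()].
#' @param lambda_wd non-negative decay coefficient \eqn{\lambda}.
#' @return list with `penalty` (scalar \eqn{\lambda \sum w^2} over unfrozen
#'   entries) and `grad_contrib` (named list, `2 * lambda_wd * w` for unfrozen
#'   entries, zeros for frozen ones).
#' @export
l2_penalty_and_grad <- function(params, lambda_wd) {
  stopifnot(inherits(params, "param_block"))
  if (!is.numeric(lambda_wd) || length(lambda_wd) != 1L || lambda_wd < 0)
    stop("`lambda_wd` must be a non-negative scalar")
  grad <- zeros_like(params)
  penalty <- 0
  for (nm in active_names(params)) {
    w <- params$entries[[nm]]
    penalty <- penalty + lambda_wd * sum(w * w)
    grad[[nm]] <- 2 * lambda_wd * w
  }
  list(penalty = penalty, grad_contrib = grad)
}

# Add two shape-matched gradient lists.
add_gradients <- function(a, b) {
  for (nm in names(a)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
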