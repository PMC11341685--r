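#' Per-epoch learning-rate schedule
#'
#' SAdagrad distinguishes itself from plain Adagrad by drawing its base step
#' size from a precomputed per-epoch table LS rather than using a single
#' constant. The table follows a harmonic (inverse-time) decay clipped from
#' below:
#' \deqn{LS(e) = \max\left(\frac{\eta_0}{1 + \gamma e},\ \eta_{floor}\right)}
#' so the base rate gradually shrinks but never vanishes. Epochs beyond the
#' precomputed horizon are served by the closed form, never an error.
#'
#' @param eta0 initial learning rate \eqn{\eta_0} (default 0.01).
#' @param decay non-negative harmonic decay coefficient \eqn{\gamma}
#'   (default 0.05 per epoch).
#' @param floor non-negative lower clip \eqn{\eta_{floor}} (default
#'   `eta0 / 100`); must not exceed `eta0`.
#' @param horizon number of epochs to precompute (>= 1).
#' @return an object of class `lr_schedule` with fields `eta0`, `decay`,
#'   `floor`, `horizon` and the precomputed `table`.
#' @examples
#' sc <- build_schedule(0.01, decay = 0.05)
#' rate_at_epoch(sc, 20) # 0.01 / (1 + 1) = 0.005
#' @export
build_schedule <- function(eta0 = 0.01, decay = 0.05, floor = eta0 / 100,
                           horizon = 200L) {
  if (!is.numeric(eta0) || length(eta0) != 1L || eta0 <= 0)
    stop("`eta0` must be a positive scalar")
  if (decay < 0) stop("`decay` must be non-negative")
  if (floor < 0) stop("`floor` must be non-negative")
  if (floor > eta0) stop("`floor` must not exceed `eta0`")
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("`horizon` must be at least 1")
  e <- seq_len(horizon) - 1L
  structure(list(eta0 = eta0, decay = decay, floor = floor, horizon = horizon,
                 table = pmax(eta0 / (1 + decay * e), floor)),
            class = "lr_schedule")
}

#' Query the schedule at an epoch
#'
#' Returns the tabulated rate for epochs inside the horizon and the closed
#' form \eqn{\max(\eta_0/(1+\gamma e), \eta_{floor})} beyond it.
#'
#' @param sched an [build_schedule()] object.
#' @param e epoch index (integer >= 0); vectorized.
#' @return the per-epoch base learning rate(s), always >= `floor`.
#' @export
rate_at_epoch <- function(sched, e) {
  stopifnot(inherits(sched, "lr_schedule"))
  if (any(e < 0)) stop("epoch index must be non-negative")
  pmax(sched$eta0 / (1 + sched$decay * e), sched$floor)
}

#' @export
print.lr_schedule <- function(x, ...) {
  cat(sprintf(
    "<lr_schedule> LS(e) = max(%g / (1 + %g e), %g), horizon %d\n",
    x$eta0, x$decay, x$floor, x$horizon))
  invisible(x)
}
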