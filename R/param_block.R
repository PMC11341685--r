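#' Parameter block
#'
#' A named collection of real-valued arrays being optimized, with an optional
#' set of frozen entries. Frozen entries realize transfer-learning style
#' fine-tuning: no optimizer step ever touches them (nor their optimizer-state
#' slots), so a frozen feature extractor stays bitwise identical to its
#' initial value while the head trains.
#'
#' @param entries named list of numeric vectors/matrices/arrays. Names must be
#'   unique and non-empty.
#' @param frozen character vector of entry names excluded from updates.
#' @return an object of class `param_block`.
#' @examples
#' pb <- param_block(list(w = matrix(0, 2, 3), b = numeric(3)))
#' pb <- set_frozen(pb, "w")
#' @export
param_block <- function(entries, frozen = character()) {
  if (!is.list(entries) || length(entries) == 0L)
    stop("`entries` must be a non-empty named list of numeric arrays")
  nms <- names(entries)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop("`entries` must have unique non-empty names")
  for (nm in nms) {
    if (!is.numeric(entries[[nm]]))
      stop("entry '", nm, "' is not numeric")
    entries[[nm]] <- entries[[nm]] + 0 # force double storage
    if (anyNA(entries[[nm]]) || any(!is.finite(entries[[nm]]) & length(entries[[nm]]) > 0))
      stop("entry '", nm, "' contains non-finite values")
  }
  pb <- structure(list(entries = entries, frozen = character()),
                  class = "param_block")
  set_frozen(pb, frozen)
}

#' Freeze parameter entries
#'
#' Marks the named entries as frozen; subsequent steps of any optimizer leave
#' them (and their optimizer-state slots) unchanged. Replaces the previous
#' frozen set.
#'
#' @param params a [param_block()].
#' @param names character vector of entry names to freeze (may be empty).
#' @return the updated `param_block`.
#' @export
set_frozen <- function(params, names) {
  stopifnot(inherits(params, "param_block"))
  names <- as.character(names)
  unknown <- setdiff(names, base::names(params$entries))
  if (length(unknown) > 0L)
    stop("unknown parameter name(s) in frozen set: ",
         paste(unknown, collapse = ", "))
  params$frozen <- unique(names)
  params
}

#' @export
print.param_block <- function(x, ...) {
  cat("<param_block> ", length(x$entries), " entries, ",
      sum(vapply(x$entries, length, 1L)), " scalars\n", sep = "")
  for (nm in names(x$entries)) {
    d <- dim(x$entries[[nm]])
    if (is.null(d)) d <- length(x$entries[[nm]])
    cat("  ", nm, " [", paste(d, collapse = "x"), "]",
        if (nm %in% x$frozen) " (frozen)", "\n", sep = "")
  }
  invisible(x)
}

# Validate that `grad` (named list) shape-matches `params`; aborts with an
# input-contract error on mismatch and a numeric error naming the offending
# entry on non-finite values.
check_gradient <- function(params, grad) {
  if (!setequal(names(grad), names(params$entries)))
    stop("gradient key set does not match parameter names")
  for (nm in names(params$entries)) {
    g <- grad[[nm]]
    p <- params$entries[[nm]]
    if (length(g) != length(p) || !identical(dim(g), dim(p)))
      stop("gradient for '", nm, "' does not shape-match the parameter")
    if (length(g) > 0 && any(!is.finite(g)))
      stop("non-finite gradient for parameter '", nm, "'")
  }
  invisible(TRUE)
}

# Names updated by optimizer steps (unfrozen).
active_names <- function(params) {
  setdiff(names(params$entries), params$frozen)
}

# Zero arrays shaped like the parameter entries.
zeros_like <- function(params) {
  lapply(params$entries, function(p) {
    z <- p
    z[] <- 0
    z
  })
}

#' Optimizer hyperparameters
#'
#' Container for the scalar hyperparameters shared by the optimizer update
#' rules: global learning rate \eqn{\eta}, numerical guard \eqn{\epsilon},
#' Adam moment decays \eqn{\beta_1,\beta_2}, and the L2 weight-decay
#' coefficient \eqn{\lambda}.
#'
#' @param eta positive global learning rate.
#' @param epsilon small positive guard against division by zero.
#' @param beta1,beta2 Adam exponential-decay rates, each in \[0, 1).
#' @param lambda_wd non-negative L2 weight-decay coefficient.
#' @return an object of class `hyper_params`.
#' @seealso [default_hyperparams()] for the conventional per-optimizer
#'   defaults.
#' @export
hyper_params <- function(eta = 0.01, epsilon = 1e-8, beta1 = 0.9,
                         beta2 = 0.999, lambda_wd = 0) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0)
    stop("`eta` must be a positive finite scalar")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("`epsilon` must be a positive scalar")
  if (beta1 < 0 || beta1 >= 1) stop("`beta1` must lie in [0, 1)")
  if (beta2 < 0 || beta2 >= 1) stop("`beta2` must lie in [0, 1)")
  if (lambda_wd < 0) stop("`lambda_wd` must be non-negative")
  structure(list(eta = eta, epsilon = epsilon, beta1 = beta1, beta2 = beta2,
                 lambda_wd = lambda_wd),
            class = "hyper_params")
}

#' Conventional default hyperparameters per optimizer
#'
#' Adagrad and SAdagrad start from a global rate of 0.01; Adam uses the usual
#' (0.001, 0.9, 0.999, 1e-8); SGD shares the 0.01 default.
#'
#' @param optimizer one of `"sgd"`, `"adagrad"`, `"adam"`, `"sadagrad"`.
#' @return a [hyper_params()] object.
#' @export
default_hyperparams <- function(optimizer = c("sgd", "adagrad", "adam",
                                              "sadagrad")) {
  optimizer <- match.arg(optimizer)
  switch(optimizer,
    adam = hyper_params(eta = 0.001),
    hyper_params(eta = 0.01))
}
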