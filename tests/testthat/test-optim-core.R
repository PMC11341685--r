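test_that("SGD step applies the fixed-rate rule and respects freezing", {
  pb <- param_block(list(theta = 1.0))
  out <- sgd_step(pb, list(theta = 0.5), hyper_params(eta = 0.01))
  expect_equal(out$entries$theta, 0.995)

  # zero gradient is the identity
  pb <- toy_params()
  g0 <- lapply(pb$entries, function(e) { e[] <- 0; e })
  expect_identical(sgd_step(pb, g0)$entries, pb$entries)

  # frozen entry untouched even under a nonzero gradient
  pb <- set_frozen(param_block(list(theta = 1.0)), "theta")
  out <- sgd_step(pb, list(theta = 1.0), hyper_params(eta = 0.01))
  expect_identical(out$entries$theta, 1.0)
})

test_that("Adagrad accumulates squared gradients and rescales the step", {
  pb <- param_block(list(theta = 0.5))
  st <- adagrad_state_init(pb)
  hp <- hyper_params(eta = 0.01, epsilon = 1e-8)
  out <- adagrad_step(pb, list(theta = 2.0), st, hp)
  expect_equal(out$state$accumulator$theta, 4.0)
  expect_equal(out$params$entries$theta, 0.5 - 0.01 / sqrt(4 + 1e-8) * 2,
               tolerance = 1e-12)
  # effective rate is exposed in the metadata
  expect_equal(out$meta$effective_rate$theta, 0.01 / sqrt(4 + 1e-8),
               tolerance = 1e-15)

  # zero gradient leaves both parameter and accumulator unchanged
  out0 <- adagrad_step(pb, list(theta = 0), adagrad_state_init(pb), hp)
  expect_identical(out0$params$entries$theta, 0.5)
  expect_identical(out0$state$accumulator$theta, 0)

  # two unit-gradient steps accumulate to exactly 2
  st <- adagrad_state_init(pb)
  s1 <- adagrad_step(pb, list(theta = 1), st, hp)
  s2 <- adagrad_step(s1$params, list(theta = 1), s1$state, hp)
  expect_equal(s2$state$accumulator$theta, 2.0)
})

test_that("Adam bias correction is exact at t = 1 and the step has the
           expected magnitude", {
  pb <- param_block(list(theta = 0))
  hp <- hyper_params(eta = 0.001, beta1 = 0.9, beta2 = 0.999)
  out <- adam_step(pb, list(theta = 1), adam_state_init(pb), hp)
  expect_identical(out$state$t, 1L)
  expect_equal(out$state$m$theta, 0.1)
  expect_equal(out$meta$m_hat$theta, 1.0) # m' / (1 - beta1) == g exactly
  expect_equal(out$meta$v_hat$theta, 1.0)
  # update magnitude eta * 1 / (1 + eps)
  expect_equal(abs(out$params$entries$theta), 0.001 / (1 + 1e-8),
               tolerance = 1e-15)

  # zero gradient from a fresh state changes nothing
  out0 <- adam_step(pb, list(theta = 0), adam_state_init(pb), hp)
  expect_identical(out0$params$entries$theta, 0)
})

test_that("Adam moments approach their corrected values under constant
           gradients and the step magnitude approaches eta", {
  pb <- param_block(list(theta = 0))
  st <- adam_state_init(pb)
  hp <- hyper_params(eta = 0.001)
  g <- list(theta = -2.5)
  for (i in 1:2000) {
    prev <- pb$entries$theta
    out <- adam_step(pb, g, st, hp)
    pb <- out$params; st <- out$state
  }
  expect_equal(out$meta$m_hat$theta, st$m$theta, tolerance = 1e-10)
  expect_equal(abs(pb$entries$theta - prev), hp$eta, tolerance = 1e-6)
})

test_that("SAdagrad applies the scheduled, floored per-coordinate rate", {
  # fresh state, epoch 0, LS(0) = 0.01, unit gradient: step of ~0.01
  pb <- param_block(list(theta = 0))
  sc <- build_schedule(0.01, decay = 0.05, floor = 1e-4, horizon = 10)
  out <- sadagrad_step(pb, list(theta = 1), sadagrad_state_init(pb), sc)
  expect_equal(out$params$entries$theta, -0.01 / sqrt(1 + 1e-8),
               tolerance = 1e-12)

  # huge accumulator: raw rate 1e-6 is floored at 1e-4
  pb <- param_block(list(theta = 1))
  st <- sadagrad_state_init(pb)
  st$accumulator$theta <- 1e8
  sc0 <- build_schedule(0.01, decay = 0, floor = 1e-4, horizon = 2)
  out <- sadagrad_step(pb, list(theta = 1), st, sc0)
  expect_equal(out$meta$effective_rate$theta, 1e-4)
  expect_equal(out$params$entries$theta, 1 - 1e-4)

  # epochs beyond the schedule horizon use the closed form, never an error
  st <- sadagrad_state_init(pb, epoch = 500L)
  expect_silent(out <- sadagrad_step(pb, list(theta = 1), st, sc))
  expect_equal(out$meta$ls, rate_at_epoch(sc, 500))
})

test_that("SAdagrad effective rate respects floor and epsilon ceiling", {
  sc <- build_schedule(0.01, decay = 0.05, floor = 1e-4, horizon = 50)
  hp <- default_hyperparams("sadagrad")
  pb <- param_block(list(w = rnorm(8)))
  st <- sadagrad_state_init(pb)
  set.seed(11)
  for (i in 1:40) {
    out <- sadagrad_step(pb, list(w = rnorm(8)), st, sc, hp)
    r <- out$meta$effective_rate$w
    expect_true(all(r >= sc$floor))
    expect_true(all(r <= rate_at_epoch(sc, 0) / sqrt(hp$epsilon)))
    pb <- out$params
    st <- sadagrad_advance_epoch(out$state)
  }
  expect_identical(st$epoch, 40L)
})

test_that("Adagrad and SAdagrad accumulators are coordinate-wise
           non-decreasing over random gradient streams", {
  set.seed(3)
  for (rep in 1:10) {
    pb <- toy_params(theta = rnorm(3), w = matrix(rnorm(4), 2, 2))
    sa <- adagrad_state_init(pb)
    ss <- sadagrad_state_init(pb)
    sc <- build_schedule(horizon = 30)
    for (t in 1:30) {
      g <- random_gradient_like(pb)
      oa <- adagrad_step(pb, g, sa)
      os <- sadagrad_step(pb, g, ss, sc)
      for (nm in names(pb$entries)) {
        expect_true(all(oa$state$accumulator[[nm]] >= sa$accumulator[[nm]]))
        expect_true(all(os$state$accumulator[[nm]] >= ss$accumulator[[nm]]))
      }
      sa <- oa$state; ss <- sadagrad_advance_epoch(os$state)
      pb <- oa$params
    }
  }
})

test_that("zero-decay zero-floor SAdagrad reduces exactly to Adagrad", {
  set.seed(9)
  pb_a <- toy_params(theta = rnorm(3), w = matrix(rnorm(4), 2, 2))
  pb_s <- pb_a
  sa <- adagrad_state_init(pb_a)
  ss <- sadagrad_state_init(pb_s)
  sc <- build_schedule(eta0 = 0.01, decay = 0, floor = 0, horizon = 25)
  hp <- hyper_params(eta = 0.01)
  for (t in 1:25) {
    g <- random_gradient_like(pb_a)
    oa <- adagrad_step(pb_a, g, sa, hp)
    os <- sadagrad_step(pb_s, g, ss, sc, hp)
    pb_a <- oa$params; sa <- oa$state
    pb_s <- os$params; ss <- sadagrad_advance_epoch(os$state)
    expect_identical(pb_a$entries, pb_s$entries)
    expect_identical(sa$accumulator, ss$accumulator)
  }
})

test_that("L2 penalty and gradient follow the coupled weight-decay rule", {
  pb <- param_block(list(w = c(1, -2)))
  out <- l2_penalty_and_grad(pb, 0.1)
  expect_equal(out$penalty, 0.5)
  expect_equal(out$grad_contrib$w, c(0.2, -0.4))

  expect_equal(l2_penalty_and_grad(pb, 0)$penalty, 0)
  expect_equal(l2_penalty_and_grad(pb, 0)$grad_contrib$w, c(0, 0))

  pb0 <- param_block(list(w = c(0, 0)))
  out0 <- l2_penalty_and_grad(pb0, 0.3)
  expect_equal(out0$penalty, 0)
  expect_equal(out0$grad_contrib$w, c(0, 0))

  # frozen entries are excluded from penalty and contribution
  pbf <- set_frozen(param_block(list(a = 2, b = 3)), "a")
  outf <- l2_penalty_and_grad(pbf, 0.5)
  expect_equal(outf$penalty, 0.5 * 9)
  expect_equal(outf$grad_contrib$a, 0)

  expect_error(l2_penalty_and_grad(pb, -0.1), "non-negative")
})

test_that("freezing makes entries bitwise invariant under every optimizer", {
  set.seed(21)
  mk <- function() param_block(list(features = matrix(rnorm(6), 2, 3),
                                    head = rnorm(3)),
                               frozen = "features")
  sc <- build_schedule(horizon = 12)
  for (opt in c("sgd", "adagrad", "adam", "sadagrad")) {
    pb <- mk()
    ref <- pb$entries$features
    st <- switch(opt, adagrad = adagrad_state_init(pb),
                 adam = adam_state_init(pb),
                 sadagrad = sadagrad_state_init(pb), NULL)
    for (t in 1:10) {
      g <- random_gradient_like(pb)
      if (opt == "sgd") pb <- sgd_step(pb, g)
      else if (opt == "adagrad") {
        o <- adagrad_step(pb, g, st); pb <- o$params; st <- o$state
      } else if (opt == "adam") {
        o <- adam_step(pb, g, st); pb <- o$params; st <- o$state
      } else {
        o <- sadagrad_step(pb, g, st, sc); pb <- o$params
        st <- sadagrad_advance_epoch(o$state)
      }
    }
    expect_identical(pb$entries$features, ref)
    expect_false(identical(pb$entries$head, mk()$entries$head))
  }

  # freezing everything makes any step the identity
  pb <- set_frozen(toy_params(), c("theta", "w"))
  g <- random_gradient_like(pb)
  expect_identical(sgd_step(pb, g)$entries, pb$entries)
  expect_identical(adagrad_step(pb, g, adagrad_state_init(pb))$params$entries,
                   pb$entries)
})

test_that("input-contract errors name the offending input", {
  pb <- param_block(list(theta = c(1, 2)))
  expect_error(sgd_step(pb, list(theta = 1)), "shape-match")
  expect_error(sgd_step(pb, list(other = c(1, 2))), "key set")
  expect_error(sgd_step(pb, list(theta = c(1, NaN))), "theta")
  expect_error(set_frozen(pb, "nope"), "nope")
  expect_error(param_block(list(a = c(1, Inf))), "non-finite")
  expect_error(hyper_params(eta = -1), "eta")
  expect_error(hyper_params(beta1 = 1), "beta1")
})

test_that("weight decay shrinks the SGD fixed point toward zero", {
  run <- function(lambda) {
    pb <- param_block(list(theta = 0))
    hp <- hyper_params(eta = 0.05, lambda_wd = lambda)
    for (t in 1:2000) {
      g <- list(theta = pb$entries$theta - 3) # d/dtheta 0.5 (theta-3)^2
      wd <- l2_penalty_and_grad(pb, lambda)
      g$theta <- g$theta + wd$grad_contrib$theta
      pb <- sgd_step(pb, g, hp)
    }
    pb$entries$theta
  }
  expect_lt(abs(run(0.1)), abs(run(0)))
  expect_equal(run(0.1), 3 / (1 + 2 * 0.1), tolerance = 1e-6)
})
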