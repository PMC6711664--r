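test_that("linear network relaxes to the closed-form fixed point", {
  # k = 0, no recurrence: steady state equals the input
  p <- network_params(3, adapt_strength = 0, adaptation_enabled = FALSE)
  tr <- simulate_network(p, drive = c(1, 2, 3), duration = 200,
                         initial_state = list(rates = c(0, 0, 0)))
  expect_equal(tr$rates[, ncol(tr$rates)], c(1, 2, 3), tolerance = 1e-10)

  # with adaptation: r* = I / (1 - w_R + k), run 20 * max(tau)
  p <- network_params(2, adapt_strength = 1.8)
  tr <- simulate_network(p, drive = c(2.8, 2.8), duration = 20 * 200,
                         initial_state = list(rates = c(0, 0),
                                              adaptation = c(0, 0)))
  expect_equal(tr$rates[, ncol(tr$rates)], c(1, 1), tolerance = 1e-6)

  # nonzero w_R through the uniform weights
  p <- network_params(4, adapt_strength = 1.8, recurrent_scale = 0.5)
  tr <- simulate_network(p, drive = rep(2.3, 4), duration = 20 * 200,
                         initial_state = list(rates = rep(0, 4),
                                              adaptation = rep(0, 4)))
  expect_equal(tr$rates[, ncol(tr$rates)], rep(2.3 / (1 - 0.5 + 1.8), 4),
               tolerance = 1e-6)
})

test_that("superposition holds for the linear transfer", {
  set.seed(5)
  n <- 8
  p <- network_params(n, adapt_strength = 1.8)
  W <- matrix(rnorm(n * n, sd = 0.1 / n), n, n)
  w1 <- drive_waveform(1, 1, 150, 50, offset = 0)
  w2 <- drive_waveform(2, 1.5, 300, 30)
  xi1 <- runif(n); xi2 <- runif(n)
  d1 <- function(t) xi1 * drive_value(w1, t)
  d2 <- function(t) xi2 * drive_value(w2, t)
  d12 <- function(t) d1(t) + d2(t)
  z <- list(rates = numeric(n), adaptation = numeric(n))
  t1 <- simulate_network(p, W, d1, duration = 500, initial_state = z)
  t2 <- simulate_network(p, W, d2, duration = 500, initial_state = z)
  t12 <- simulate_network(p, W, d12, duration = 500, initial_state = z)
  scale <- max(abs(t12$rates))
  expect_lt(max(abs(t12$rates - t1$rates - t2$rates)) / scale, 1e-9)
})

test_that("halving dt shrinks the error consistently with first-order Euler", {
  n <- 3
  w <- drive_waveform(1, 1, 150, 50, offset = 0)
  drv <- function(t) c(1, 2, 3) * drive_value(w, t)
  run <- function(dt) {
    p <- network_params(n, adapt_strength = 1.8, dt = dt)
    simulate_network(p, drive = drv, duration = 300,
                     initial_state = list(rates = numeric(n),
                                          adaptation = numeric(n)))
  }
  ref <- run(0.03125)
  at_end <- function(tr) tr$rates[, ncol(tr$rates)]
  e1 <- max(abs(at_end(run(0.5)) - at_end(ref)))
  e2 <- max(abs(at_end(run(0.25)) - at_end(ref)))
  # first-order convergence: halving dt roughly halves the error
  expect_lt(e2, e1)
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3)
})

test_that("instability aborts with a diagnostic naming the first bad step", {
  p <- network_params(2, adapt_strength = 0, adaptation_enabled = FALSE)
  W <- matrix(1e8, 2, 2)
  expect_error(
    simulate_network(p, W, drive = c(1e300, 1e300), duration = 50,
                     initial_state = list(rates = c(1, 1))),
    "non-finite at step")
})

test_that("short-term depression resources behave and stay in (0, 1]", {
  # zero depletion: resources pinned at 1 and dynamics equal the plain network
  p <- network_params(3, adaptation_enabled = FALSE)
  w <- drive_waveform(1, 1, 150, 50, offset = 0)
  drv <- function(t) c(1, 2, 3) * drive_value(w, t)
  W <- matrix(0.1 / 3, 3, 3)
  z <- list(rates = numeric(3))
  tstd <- simulate_std_network(p, W, drv, duration = 300,
                               depletion_strength = 0, initial_state = z)
  tpl <- simulate_network(p, W, drv, duration = 300, initial_state = z)
  expect_equal(tstd$resources, matrix(1, 3, ncol(tstd$resources)))
  expect_equal(tstd$rates, tpl$rates, tolerance = 1e-12)

  # clamped rate: x* = 1/(1 + gamma*tau_x*r); gamma*tau_x*r = 1 gives 0.5
  p1 <- network_params(1, adaptation_enabled = FALSE)
  tr <- simulate_std_network(p1, matrix(0, 1, 1), drive = 2,
                             duration = 4000, tau_recover = 200,
                             depletion_strength = 1 / (200 * 2),
                             initial_state = list(rates = 2))
  expect_equal(tr$resources[1, ncol(tr$resources)], 0.5, tolerance = 1e-6)

  # property: resources in (0, 1] across random draws
  set.seed(77)
  for (i in 1:50) {
    n <- sample(2:4, 1)
    gam <- runif(1, 0, 0.5)
    taux <- runif(1, 20, 400)
    amp <- runif(n, 0, 6)
    ppar <- network_params(n, adaptation_enabled = FALSE)
    Wr <- matrix(runif(n * n, 0, 0.3 / n), n, n)
    tr <- simulate_std_network(ppar, Wr, function(t) amp * drive_value(w, t),
                               duration = 400, tau_recover = taux,
                               depletion_strength = gam,
                               initial_state = list(rates = numeric(n)))
    expect_true(all(tr$resources > 0 & tr$resources <= 1))
  }
})

test_that("the example-network protocol reproduces the learning signature", {
  # Hebbian recurrent potentiation + feedforward depression + adaptation:
  # the late-phase average drops with learning while the most selective
  # unit's peak grows.
  cfg <- preset_network(seed = 1, n_units = 2000)
  pre <- simulate_network(cfg$params, cfg$weights_pre, cfg$drive_pre,
                          duration = 350)
  post <- simulate_network(cfg$params, cfg$weights_post, cfg$drive_post,
                           duration = 350)
  late <- pre$times >= 200
  expect_lt(mean(colMeans(post$rates)[late]),
            mean(colMeans(pre$rates)[late]))
  top <- which.max(cfg$selectivity)
  expect_gt(max(post$rates[top, ]), max(pre$rates[top, ]))
  # baseline solved from the closed-form fixed point
  expect_equal(pre$rates[, 1], rep(5, 2000), tolerance = 1e-12)
})
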