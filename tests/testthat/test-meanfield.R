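test_that("zero plasticity coefficients decouple the learned block", {
  w <- drive_waveform(6, 5, 700, 40)
  p <- meanfield_params(adapt_strength = 1.8, drive_mean = w,
                        fgbar_R = 0, fbar_R = 0, fbar_F = 0, fgbar_F = 0)
  tr4 <- simulate_meanfield(p, 500, learned = TRUE)
  tr2 <- simulate_meanfield(p, 500, learned = FALSE)
  expect_equal(tr4$m, rep(0, length(tr4$m)))
  expect_equal(tr4$n, rep(0, length(tr4$n)))
  expect_equal(tr4$rbar, tr2$rbar, tolerance = 1e-14)
  expect_equal(tr4$abar, tr2$abar, tolerance = 1e-14)
})

test_that("a constant added to the mean drive shifts the fixed point linearly", {
  for (w_R in c(0, -0.4)) {
    p0 <- meanfield_params(recurrent_scale = w_R, adapt_strength = 1.8,
                           drive_mean = 2)
    p1 <- meanfield_params(recurrent_scale = w_R, adapt_strength = 1.8,
                           drive_mean = 2 + 0.7)
    t0 <- simulate_meanfield(p0, 6000, learned = FALSE)
    t1 <- simulate_meanfield(p1, 6000, learned = FALSE)
    shift <- t1$rbar[length(t1$rbar)] - t0$rbar[length(t0$rbar)]
    expect_equal(shift, 0.7 / (1 - w_R + 1.8), tolerance = 1e-6)
  }
})

test_that("the fitted preset gives a familiar rebound absent from novel", {
  p <- preset_meanfield()
  nov <- simulate_meanfield(p, 700, learned = FALSE)
  fam <- simulate_meanfield(p, 700, learned = TRUE)
  prom <- 1e-3 * diff(range(nov$rbar))
  pk_nov <- local_maxima(nov$rbar, prom)
  pk_fam <- local_maxima(fam$rbar, prom)
  expect_length(pk_nov, 1L)          # single transient, monotone after peak
  expect_gt(length(pk_fam), 1L)      # damped oscillation: at least one rebound
  # average response decreases after learning in the late phase
  late <- nov$times >= 200
  expect_lt(mean(fam$rbar[late]), mean(nov$rbar[late]))
})

test_that("global inhibition cannot generate a damped oscillation in m", {
  # constant overlap drive: first-order relaxation, no overshoot
  p <- meanfield_params(adapt_strength = 1.8, fgbar_R = 0.5, drive_m = 2)
  tr <- simulate_global_inhibition(p, 1000)
  fp <- 2 / (1 - 0.5)
  expect_true(all(diff(tr$m) >= -1e-12))
  expect_equal(tr$m[length(tr$m)], fp, tolerance = 1e-4)
  expect_length(local_maxima(tr$m, 1e-6), 0L)

  # zero inhibition strength: rbar is the plain leaky integrator
  p0 <- meanfield_params(adapt_strength = 0, drive_mean = 1.5)
  tr0 <- simulate_global_inhibition(p0, 100)
  # closed form for Euler: r_{s+1} = r_s + dt/tau (I - r_s)
  rho <- 1 - p0$dt / p0$tau_rate
  steps <- length(tr0$times) - 1L
  expect_equal(tr0$rbar[steps + 1L], 1.5 * (1 - rho^steps), tolerance = 1e-12)

  # with the fitted drive shapes and strong potentiation, m rises and falls
  # once: no rebound, unlike the private-adaptation model
  pf <- preset_meanfield()
  gi <- simulate_global_inhibition(pf, 700)
  ad <- simulate_meanfield(pf, 700, learned = TRUE)
  prom <- 1e-3 * diff(range(ad$m))
  expect_length(local_maxima(gi$m, prom), 1L)
  expect_gt(length(local_maxima(ad$m, prom)), 1L)
})

test_that("reduced short-term depression has the predicted fixed points", {
  # no depletion: linear fixed point I / (1 - fg)
  tr <- simulate_std_reduced(0.5, 0, drive = 1.2, duration = 500)
  expect_equal(tr$rate[length(tr$rate)], 1.2 / (1 - 0.5), tolerance = 1e-6)
  expect_equal(tr$resources, rep(1, length(tr$resources)))

  # joint fixed point: choose drive so r* = 1 with gamma*tau_x*r* = 1
  # r* = fg * x* * r* + I with x* = 0.5  =>  I = r*(1 - fg/2)
  fg <- 0.8; taux <- 200; gam <- 1 / taux
  tr <- simulate_std_reduced(fg, gam, tau_recover = taux,
                             drive = 1 - fg / 2, duration = 6000)
  expect_equal(tr$rate[length(tr$rate)], 1, tolerance = 1e-5)
  expect_equal(tr$resources[length(tr$resources)], 0.5, tolerance = 1e-5)

  expect_error(simulate_std_reduced(-1, 0.1, drive = 1, duration = 10),
               "fg_strength")
})

test_that("the best-fit depression model produces no strong rebound", {
  w <- drive_waveform(5, 5, 400, 20, offset = 0)
  tr <- simulate_std_reduced(2.56, 0.125, tau_rate = 5, tau_recover = 200,
                             drive = w, duration = 700)
  # no local maximum after the global peak reaches 10% of its height above
  # the intervening minimum (the fast onset transient before the global
  # peak is not a rebound)
  g <- which.max(tr$rate)
  later <- local_maxima(tr$rate, min_prominence = 0.1 * tr$rate[g])
  expect_length(later[later > g], 0L)

  # contrast: the adaptation model at its fitted parameters does rebound
  ad <- simulate_meanfield(preset_meanfield(), 700, learned = TRUE)
  g2 <- which.max(ad$m)
  reb <- local_maxima(ad$m, min_prominence = 0.1 * ad$m[g2])
  expect_gt(length(reb[reb > g2]), 0L)
})

test_that("competition decouples without mutual inhibition", {
  cp <- preset_competition()
  both <- simulate_competition(cp$params, 0, cp$transfer, cp$onsets,
                               duration = 1200)
  # each population equals the single-stimulus overlap dynamics on its clock
  single <- simulate_meanfield(cp$params, 1200, learned = TRUE)
  expect_equal(both$m[1, ], single$m, tolerance = 1e-12)
  i_on <- which(both$times == cp$onsets[2])
  n_rest <- length(both$times) - i_on + 1L
  expect_equal(both$m[2, i_on:length(both$times)], single$m[1:n_rest],
               tolerance = 1e-12)
  # silent before its onset
  expect_true(all(both$m[2, 1:(i_on - 1L)] == 0))
})

test_that("successive novel presentations suppress the second peak", {
  ps <- preset_meanfield(successive = TRUE)
  novs <- simulate_meanfield(ps, 450, learned = FALSE)
  t <- novs$times
  p1 <- max(novs$rbar[t < 150])
  p2 <- max(novs$rbar[t >= 150 & t < 400])
  expect_lt(p2, p1)
})

test_that("population averages of a full network match the mean-field system", {
  # reduced-size version of the equivalence property (the acceptance suite
  # runs it at N = 500): linear transfer, zero-sum pre-dependence
  set.seed(8)
  for (rep in 1:5) {
    N <- 60
    xi <- rgamma(N, shape = 3)
    alpha <- runif(1, 0.2, 0.95)
    rule <- hebbian_delta(xi, alpha, as_rule = TRUE)
    gF <- xi - mean(xi)
    fF <- rep(runif(1, -1, 0), N)
    ruleF <- separable_rule(fF, gF, normalize_by_n = TRUE, zero_sum = TRUE)
    ci <- runif(1, 1, 3) + runif(1, 0.2, 0.8) * xi
    wave <- drive_waveform(1, 1, 150, 50, offset = 0)
    co <- meanfield_coefficients(rule, ruleF, external_input = ci)
    W <- separable_delta(rule)
    dW_F <- separable_delta(ruleF)
    drive_fun <- function(t) {
      I <- ci * drive_value(wave, t)
      I + drop(dW_F %*% I)
    }
    np <- network_params(N, adapt_strength = 1.8, dt = 0.5)
    tr <- simulate_network(np, W, drive_fun, duration = 600,
                           initial_state = list(rates = numeric(N),
                                                adaptation = numeric(N)))
    mp <- meanfield_params(
      adapt_strength = 1.8, fgbar_R = co$fgbar_R, fbar_R = co$fbar_R,
      fbar_F = co$fbar_F, fgbar_F = co$fgbar_F,
      drive_mean = function(t) co$input_mean * drive_value(wave, t),
      drive_m = function(t) co$input_m * drive_value(wave, t),
      drive_f = function(t) co$input_f * drive_value(wave, t), dt = 0.5)
    mf <- simulate_meanfield(mp, 600)
    rbar_net <- colMeans(tr$rates)
    m_net <- colMeans(rule$pre_dependence * tr$rates)
    expect_lt(max(abs(rbar_net - mf$rbar)) / max(abs(mf$rbar)), 1e-6)
    expect_lt(max(abs(m_net - mf$m)) / max(abs(mf$m)), 1e-6)
  }
})
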