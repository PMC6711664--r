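test_that("eigenvalues match the closed form and a numeric eigensolver", {
  # k = 0: triangular system, eigenvalues on the diagonal
  lam <- eigenvalues_2d(0.4, 0, 5, 200)
  expect_equal(sort(Re(lam)), sort(c((0.4 - 1) / 5, -1 / 200)))
  expect_equal(Im(lam), c(0, 0))

  # generic cross-check against base::eigen
  set.seed(21)
  for (i in 1:20) {
    w <- runif(1, -1, 1.3); k <- runif(1, 0, 3)
    tR <- runif(1, 1, 20); tA <- runif(1, 20, 500)
    A <- matrix(c((w - 1) / tR, 1 / tA, -k / tR, -1 / tA), 2, 2)
    ref <- eigen(A, only.values = TRUE)$values
    got <- eigenvalues_2d(w, k, tR, tA)
    expect_equal(sort(Re(got)), sort(Re(ref)), tolerance = 1e-12)
    expect_equal(sort(abs(Im(got))), sort(abs(Im(ref))), tolerance = 1e-12)
  }

  # fitted parameters: lambda = -0.0125 +/- 0.041758i per the closed form
  lam <- eigenvalues_2d(0.9, 1.8, 5, 200)
  expect_equal(Re(lam[1]), -0.0125)
  expect_equal(abs(Im(lam[1])), sqrt(4 * 1.8 / 1000 - 0.015^2) / 2)
  expect_equal(abs(Im(lam[1])), 0.04175823, tolerance = 1e-6)

  # marginal stability when the feedback reaches 1 + tau_R/tau_A
  lam <- eigenvalues_2d(1 + 5 / 200, 1.8, 5, 200)
  expect_equal(Re(lam), c(0, 0), tolerance = 1e-15)
})

test_that("regime labels and the separatrix are consistent", {
  # learned block at the fitted parameters: damped oscillation
  rep5 <- classify_regime(0.9, 1.8, 5, 200)
  expect_equal(rep5$label, "stable_focus")
  expect_equal(rep5$period, 2 * pi / abs(Im(rep5$eigenvalues[1])))

  # pre-learning block: no oscillation (positive discriminant)
  rep0 <- classify_regime(0, 1.8, 5, 200)
  expect_equal(rep0$label, "stable_node")
  expect_gt(rep0$discriminant, 0)

  # the zero-discriminant boundary is classified as a node by convention;
  # build it exactly from the separatrix parabola
  k_b <- separatrix_k(0.5, 5, 200)
  rep_b <- classify_regime(0.5, k_b, 5, 200)
  expect_equal(rep_b$discriminant, 0, tolerance = 1e-15)
  expect_equal(rep_b$label, "stable_node")

  # separatrix matches root finding on the discriminant
  for (w in c(-0.5, 0.2, 0.9)) {
    k_root <- uniroot(function(k)
      classify_regime(w, k, 5, 200)$discriminant,
      interval = c(1e-8, 50), tol = 1e-12)$root
    expect_equal(separatrix_k(w, 5, 200), k_root, tolerance = 1e-8)
  }

  # instability beyond the printed bounds
  expect_equal(classify_regime(1.5, 1.8, 5, 200)$label, "unstable")
  expect_equal(classify_regime(3.2, 2, 5, 200)$label, "unstable")

  # phase diagram agrees with pointwise classification
  pd <- phase_diagram(c(0, 0.9), c(0.5, 1.8), 5, 200)
  expect_equal(nrow(pd), 4L)
  expect_equal(pd$label[pd$feedback == 0.9 & pd$k == 1.8], "stable_focus")
})

test_that("regime labels match simulated impulse responses", {
  # property check at reduced draw count (the acceptance suite uses 200)
  set.seed(31)
  used <- 0L
  for (i in 1:60) {
    repeat {
      fg <- runif(1, -1, 1.2); k <- runif(1, 0.05, 3)
      tR <- runif(1, 2, 20); tA <- runif(1, 50, 400)
      rp <- classify_regime(fg, k, tR, tA)
      if (rp$label != "unstable") break
    }
    scale_ <- ((fg - 1) / tR + 1 / tA)^2 + 4 * k / (tR * tA)
    if (abs(rp$discriminant) < 0.05 * scale_) next
    used <- used + 1L
    p <- meanfield_params(adapt_strength = k, tau_rate = tR, tau_adapt = tA,
                          fgbar_R = fg, dt = 0.2)
    tr <- simulate_meanfield(p, 4000, learned = TRUE, init = c(0, 0, 1, 0))
    sgn <- sign(tr$m)
    sgn <- sgn[abs(tr$m) >= 1e-12]
    osc <- sum(diff(sgn) != 0) >= 2
    expect_equal(osc, rp$label == "stable_focus",
                 info = sprintf("fg=%.3f k=%.3f tR=%.2f tA=%.1f", fg, k, tR, tA))
    # period within 3% for strongly oscillatory draws
    if (rp$label == "stable_focus") {
      lam <- rp$eigenvalues[1]
      if (abs(Im(lam) / Re(lam)) > 2) {
        pm <- dominant_period(tr$m, 0.2)
        if (!is.na(pm))
          expect_lt(abs(pm - rp$period) / rp$period, 0.03)
      }
    }
  }
  expect_gt(used, 30L)
})

test_that("second-peak condition matches its piecewise-linear simulation", {
  # adaptation is necessary: with k = 0 the second peak is r0 + r1
  sp <- second_peak_condition(2, 0.5, 50, 200, w_R = 0, k = 0,
                              tau_rate = 5, tau_adapt = 200)
  expect_equal(sp$second_peak, 2 + 0.5)
  expect_false(sp$satisfied)

  # long-decay limit: accumulated adaptation tends to r1
  sp <- second_peak_condition(2, 0.5, 50, 1e9, w_R = 0, k = 1.8,
                              tau_rate = 5, tau_adapt = 200)
  expect_equal(sp$a1, 0.5, tolerance = 1e-6)

  expect_error(second_peak_condition(2, 0.5, 0, 100, 0, 1.8, 5, 200),
               "positive")
  expect_error(second_peak_condition(2, 0.5, 50, 100, 1.2, 1.8, 5, 200),
               "w_R < 1")

  # oracle: integrate the adaptation numerically under the clamped linear
  # decay (fine Euler) and reassemble the peak; the satisfied flag must
  # agree away from the boundary
  set.seed(41)
  agree <- 0L; used <- 0L
  for (i in 1:100) {
    r0 <- runif(1, 0.5, 3); r1 <- runif(1, 0, r0)
    t0 <- runif(1, 20, 100); t1 <- runif(1, 50, 400)
    k <- runif(1, 0.5, 3); tR <- runif(1, 2, 10); tA <- runif(1, 100, 300)
    wR <- runif(1, -0.5, 0.5)
    an <- second_peak_condition(r0, r1, t0, t1, wR, k, tR, tA)
    if (abs(an$second_peak - r0) < 0.05 * max(r0, 1)) next
    used <- used + 1L
    dt <- 0.01
    nb <- round(t1 / dt)
    rs <- r0 + (r1 - r0) * (seq_len(nb) - 0.5) / nb
    a <- 0
    for (s in seq_len(nb)) a <- a + dt / tA * (rs[s] - a)
    expect_equal(a, an$a1, tolerance = 1e-3)
    peak2 <- (an$I0 - a * k) * t0 / an$tau_eff + r1
    agree <- agree + ((peak2 < r0) == an$satisfied)
  }
  expect_gte(agree / used, 0.95)
})
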