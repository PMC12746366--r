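test_that("the three-parameter recovery signal evaluates correctly", {
  expect_equal(model1_signal(c(1, 100, 1e6), 2, 0, 300), rep(2, 3))
  expect_equal(model1_signal(1e9, 1.5, 0.9, 300), 1.5)
  expect_equal(model1_signal(300, 2, 1, 300), 2 * (1 - exp(-1)))
  expect_equal(model1_signal(300, 2, 1, 300), 1.26424, tolerance = 1e-5)
})

test_that("Model 1 recovers exact parameters and handles degenerate series", {
  ts <- c(25, 50, 300, 600, 10000)
  series <- data.frame(ts_ms = ts, amplitude = model1_signal(ts, 1, 0.9, 250))
  f <- fit_model1(series, "selective")
  expect_true(f$valid)
  expect_lt(abs(f$M0 - 1), 1e-6)
  expect_lt(abs(f$k - 0.9), 1e-6)
  expect_lt(abs(f$T1_ms - 250) / 250, 1e-6)
  expect_gt(f$r_squared, 1 - 1e-10)

  const <- data.frame(ts_ms = ts, amplitude = rep(2, 5))
  fc <- fit_model1(const)
  expect_true(fc$valid)
  expect_equal(fc$k, 0)
  expect_true(is.na(fc$T1_ms))   # T1 unidentifiable without saturation

  short <- data.frame(ts_ms = ts[1:3], amplitude = model1_signal(ts[1:3], 1, 0.9, 250))
  expect_false(fit_model1(short)$valid)
})

test_that("Model 1 fit quality on noisy recovery curves matches the in-vivo range", {
  ts <- c(25, 50, 300, 600, 10000)
  set.seed(14)
  r2 <- replicate(20, {
    y <- model1_signal(ts, 1, 0.85, 150) + rnorm(5, 0, 0.04)
    fit_model1(data.frame(ts_ms = ts, amplitude = y))$r_squared
  })
  expect_gt(mean(r2), 0.96)
})

test_that("apparent T1 ratio behaves as an exchange marker", {
  ts_s <- c(25, 50, 300, 600, 10000)
  ts_b <- c(500, 1000, 2000, 4000, 10000)
  ratio_for <- function(sigma) {
    p <- two_spin_params(600, sigma, k_sel = 0.85, k_broad = 0.85)
    sel <- data.frame(ts_ms = ts_s, amplitude = two_spin_solve(p, "selective", ts_s))
    bro <- data.frame(ts_ms = ts_b, amplitude = two_spin_solve(p, "broadband", ts_b))
    apparent_t1_ratio(fit_model1(bro, "broadband"), fit_model1(sel, "selective"))
  }
  r0 <- ratio_for(0)
  expect_equal(r0, 1, tolerance = 1e-3)             # no exchange: ratio 1
  ratios <- vapply(c(4, 8, 12, 16), ratio_for, numeric(1))
  expect_true(all(diff(c(r0, ratios)) > 0))          # monotone in sigma
  expect_gt(ratios[3], 5)                            # TRP-like: ratio >> 1

  f1 <- fit_model1(data.frame(ts_ms = ts_s,
                              amplitude = model1_signal(ts_s, 1, 0.9, 250)))
  bad <- f1; bad$valid <- FALSE
  expect_identical(apparent_t1_ratio(f1, f1), 1)
  expect_true(is.na(apparent_t1_ratio(bad, f1)))
})

test_that("the Solomon right-hand side has the correct structure", {
  p <- two_spin_params(622.3, 12.3, M0_A = 2, k_sel = 0.85, k_broad = 0.85)
  expect_equal(two_spin_rhs(c(p$M0_A, p$M0_B), p), c(0, 0))  # fixed point

  p0 <- two_spin_params(500, 0, M0_A = 2)
  st <- c(1.2, p0$M0_B * 0.5)
  d <- two_spin_rhs(st, p0)
  expect_equal(d[1], (2 - 1.2) * 2)  # -a/T1_A with a = -0.8, T1_A = 0.5 s
  expect_equal(d[2], (p0$M0_B - st[2]) * (1000 / 1800))

  # units: sigma in Hz and T1 in ms combine to units/s
  p1 <- two_spin_params(1000, 2, M0_A = 1)
  a <- -0.5  # Mz_A - M0_A
  d1 <- two_spin_rhs(c(1 + a, p1$M0_B), p1)
  expect_equal(d1[1], -(1 + 2) * a)
})

test_that("the closed-form solver honors initial conditions and the exchange-free limit", {
  p <- two_spin_params(622.3, 12.3, M0_A = 2, k_sel = 0.8, k_broad = 0.6)
  sel0 <- two_spin_solve(p, "selective", 0, return_both = TRUE)
  expect_equal(as.numeric(sel0), c(2 * (1 - 0.8), p$M0_B))
  bro0 <- two_spin_solve(p, "broadband", 0, return_both = TRUE)
  expect_equal(as.numeric(bro0), c(2 * (1 - 0.6), p$M0_B * (1 - 0.6)))

  ts <- c(0, 25, 50, 300, 600, 2000, 10000)
  p0 <- two_spin_params(924.9, 0, M0_A = 1.7, k_sel = 0.85, k_broad = 0.85)
  expect_equal(two_spin_solve(p0, "selective", ts),
               model1_signal(ts, 1.7, 0.85, 924.9), tolerance = 1e-14)
  expect_equal(two_spin_solve(p0, "broadband", ts),
               model1_signal(ts, 1.7, 0.85, 924.9), tolerance = 1e-14)

  # defective-matrix edge: identical pool relaxation rates, no exchange
  pd <- two_spin_params(1800, 0, M0_A = 1, k_sel = 0.9, k_broad = 0.9)
  expect_equal(two_spin_solve(pd, "selective", ts),
               model1_signal(ts, 1, 0.9, 1800), tolerance = 1e-10)
})

test_that("closed-form and numeric solvers agree on subject-1 tryptophan parameters", {
  p <- two_spin_params(1374.7, 15.3, M0_A = 1, k_sel = 0.85, k_broad = 0.85)
  ts <- c(25, 50, 300, 600, 500, 1000, 2000, 4000, 10000)
  for (e in c("selective", "broadband")) {
    a <- two_spin_solve(p, e, ts, "closed_form")
    b <- two_spin_solve(p, e, ts, "numeric")
    expect_lt(max(abs(a - b)), 1e-8 * p$M0_A)
  }
})

test_that("water magnetization is essentially unaffected by the metabolite", {
  p <- two_spin_params(622.3, 12.3, M0_A = 1, k_sel = 0.85, k_broad = 0.85)
  ts <- seq(0, 10000, by = 250)
  for (e in c("selective", "broadband")) {
    both <- two_spin_solve(p, e, ts, return_both = TRUE)
    k <- if (e == "broadband") p$k_broad else 0
    ref <- p$M0_B * (1 - k * exp(-ts / p$T1_B_ms))
    expect_lt(max(abs(both[, "Mz_B"] - ref)), 1e-4 * p$M0_B)
  }
})

test_that("Model 2 recovers exact parameters and degrades gracefully", {
  ts_s <- c(25, 50, 300, 600, 10000)
  ts_b <- c(500, 1000, 2000, 4000, 10000)
  p <- two_spin_params(924.9, 5.7, M0_A = 2.5, k_sel = 0.85, k_broad = 0.85)
  sel <- data.frame(ts_ms = ts_s, amplitude = two_spin_solve(p, "selective", ts_s))
  bro <- data.frame(ts_ms = ts_b, amplitude = two_spin_solve(p, "broadband", ts_b))
  f <- fit_model2(sel, bro, 0.85, 0.85, seed = 3)
  expect_true(f$valid)
  expect_lt(abs(f$T1_A_ms - 924.9) / 924.9, 0.01)
  expect_lt(abs(f$sigma_AB_hz - 5.7) / 5.7, 0.01)
  expect_lt(abs(f$M0_A - 2.5) / 2.5, 0.01)
  expect_gt(f$r_squared, 1 - 1e-10)

  # exchange-off truth: fitted sigma ~ 0 and T1 matches both experiments
  p0 <- two_spin_params(700, 0, M0_A = 1, k_sel = 0.9, k_broad = 0.8)
  sel0 <- data.frame(ts_ms = ts_s, amplitude = two_spin_solve(p0, "selective", ts_s))
  bro0 <- data.frame(ts_ms = ts_b, amplitude = two_spin_solve(p0, "broadband", ts_b))
  f0 <- fit_model2(sel0, bro0, 0.9, 0.8, seed = 3)
  expect_lt(f0$sigma_AB_hz, 0.05)
  expect_lt(abs(f0$T1_A_ms - 700) / 700, 0.01)

  expect_false(fit_model2(sel[1:2, ], bro, 0.85, 0.85, seed = 1)$valid)
})

test_that("Model 2 fitting is deterministic given a seed", {
  ts_s <- c(25, 50, 300, 600, 10000)
  ts_b <- c(500, 1000, 2000, 4000, 10000)
  p <- two_spin_params(622.3, 12.3, k_sel = 0.85, k_broad = 0.85)
  set.seed(8)
  sel <- data.frame(ts_ms = ts_s,
                    amplitude = two_spin_solve(p, "selective", ts_s) + rnorm(5, 0, 0.04))
  bro <- data.frame(ts_ms = ts_b,
                    amplitude = two_spin_solve(p, "broadband", ts_b) + rnorm(5, 0, 0.04))
  f1 <- fit_model2(sel, bro, 0.85, 0.85, seed = 77)
  f2 <- fit_model2(sel, bro, 0.85, 0.85, seed = 77)
  expect_identical(f1$sigma_AB_hz, f2$sigma_AB_hz)
  expect_identical(f1$T1_A_ms, f2$T1_A_ms)
})

test_that("broadband apparent T1 is non-decreasing in the exchange rate", {
  ts_b <- c(500, 1000, 2000, 4000, 10000)
  t1_app <- vapply(c(0, 2, 4, 8, 12, 16), function(sg) {
    p <- two_spin_params(600, sg, k_sel = 0.85, k_broad = 0.85)
    bro <- data.frame(ts_ms = ts_b, amplitude = two_spin_solve(p, "broadband", ts_b))
    fit_model1(bro, "broadband")$T1_ms
  }, numeric(1))
  expect_true(all(diff(t1_app) > -1e-6))
})
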