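test_that("instantaneous phase of canonical signals behaves analytically", {
  fs <- 1000
  t <- seq(1 / fs, 4, by = 1 / fs)
  n <- length(t)
  ctr <- round(0.1 * n):round(0.9 * n)

  # 1 Hz sinusoid: unwrapped phase slope 2*pi rad/s within 0.1%
  phi <- instantaneous_phase(sin(2 * pi * t))
  dphi <- diff(phi[ctr]) %% (2 * pi)
  slope <- mean(dphi) * fs
  expect_equal(slope, 2 * pi, tolerance = 1e-3)

  # quadrature pair: cos leads sin by pi/2
  pc <- instantaneous_phase(cos(2 * pi * 2 * t))
  ps <- instantaneous_phase(sin(2 * pi * 2 * t))
  d <- (pc - ps)[ctr] %% (2 * pi)
  expect_true(all(abs(d - pi / 2) < 1e-3))

  # linear chirp 0.5 -> 3 Hz: finite-difference frequency tracks the ramp
  dur <- 20
  tt <- seq(1 / 200, dur, by = 1 / 200)
  f_inst <- 0.5 + (3 - 0.5) * tt / dur
  x <- sin(2 * pi * (0.5 * tt + (3 - 0.5) * tt^2 / (2 * dur)))
  phi <- instantaneous_phase(x)
  ctr2 <- round(0.1 * length(tt)):round(0.9 * length(tt))
  fd <- (diff(phi) %% (2 * pi)) * 200 / (2 * pi)
  rel <- abs(fd[ctr2] - f_inst[ctr2]) / f_inst[ctr2]
  expect_lt(stats::median(rel), 0.01)

  expect_error(instantaneous_phase(rep(1, 500)), "constant")
  expect_error(instantaneous_phase(rnorm(50)), "100 samples")
})

test_that("complex_sync has the closed forms and matches brute force", {
  # constant offset pi/3
  phi <- runif(500, -pi, pi)
  v <- complex_sync(phi, phi + pi / 3)
  expect_equal(v, complex(modulus = 1, argument = pi / 3), tolerance = 1e-12)
  expect_equal(Re(v), 0.5, tolerance = 1e-12)
  expect_equal(Im(v), sqrt(3) / 2, tolerance = 1e-12)

  # alternating {0, pi} differences cancel
  d <- rep(c(0, pi), 100)
  expect_equal(Mod(complex_sync(numeric(200), d)), 0, tolerance = 1e-12)

  # brute-force agreement on random series
  set.seed(42)
  for (rep in 1:5) {
    a <- runif(400, -pi, pi); b <- runif(400, -pi, pi)
    expect_equal(complex_sync(a, b), oracle_complex_sync(a, b),
                 tolerance = 1e-12)
  }
  expect_error(complex_sync(1:5, 1:6), "length")
})

test_that("null PLV follows Rayleigh statistics and the T^(-1/2) law", {
  # E|v| for independent uniform phases = sqrt(pi / (4 T))
  set.seed(7)
  plv <- replicate(300, Mod(complex_sync(runif(10000, -pi, pi),
                                         runif(10000, -pi, pi))))
  expect_equal(mean(plv), sqrt(pi / (4 * 10000)), tolerance = 0.1)

  # log-log slope of E[PLV] vs T in [-0.55, -0.45]
  Ts <- c(1e3, 1e4, 1e5)
  m <- vapply(Ts, function(T) {
    mean(replicate(60, Mod(complex_sync(runif(T, -pi, pi),
                                        runif(T, -pi, pi)))))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(m) ~ log(Ts)))[2]
  expect_gt(slope, -0.55)
  expect_lt(slope, -0.45)
})

test_that("signed_sync_index applies the sign of cos(theta)", {
  expect_equal(as.numeric(signed_sync_index(0.9 * exp(0.1i))), 0.9,
               tolerance = 1e-12)
  expect_equal(as.numeric(signed_sync_index(0.7 * exp(3i))), -0.7,
               tolerance = 1e-12)
  # degenerate theta = pi/2: sign +1 and flagged
  V <- signed_sync_index(0.5 * exp(1i * pi / 2))
  expect_equal(as.numeric(V), 0.5, tolerance = 1e-12)
  expect_true(attr(V, "degenerate"))
  expect_false(attr(signed_sync_index(0.9 * exp(0.1i)), "degenerate"))
  expect_error(signed_sync_index(1.5 + 0i), "not a valid")
})

test_that("acceleration_correlation is Pearson's r", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 4)
  expect_equal(acceleration_correlation(x, y), oracle_pearson(x, y),
               tolerance = 1e-12)
  z <- rnorm(50)
  expect_equal(acceleration_correlation(z, z), 1, tolerance = 1e-12)
  expect_equal(acceleration_correlation(z, -z), -1, tolerance = 1e-12)
  # orthogonal quadrature over integer periods
  t <- seq(0, 2, length.out = 401)[-401]
  expect_equal(acceleration_correlation(sin(2 * pi * t), cos(2 * pi * t)), 0,
               tolerance = 1e-9)
  expect_error(acceleration_correlation(rep(1, 10), rnorm(10)),
               "zero-variance")
  expect_error(acceleration_correlation(1:5, 1:6), "length")
})

test_that("time delay of a narrow-band source shifts theta by ~ 2*pi*f*tau", {
  fs <- 500
  n <- fs * 40
  carrier_f <- 1  # band centred on 1 Hz
  for (tau in c(0.05, 0.1)) {
    set.seed(3)
    x <- band_limited_noise(n, fs, c(0.9, 1.1))
    k <- round(tau * fs)
    y <- c(x[(k + 1):n], x[1:k])  # y leads x by tau
    phi_x <- instantaneous_phase(x)
    phi_y <- instantaneous_phase(y)
    keep <- 2000:(n - 2000)
    v <- complex_sync(phi_x[keep], phi_y[keep])
    expected <- 2 * pi * carrier_f * tau
    expect_lt(abs(Arg(v) - expected) / expected, 0.05)
  }
})

test_that("all_pairs_sync covers pair presets, symmetry and invariants", {
  rec <- generate_recording(small_cluster_spec(seed = 19))
  pre <- preprocess_recording(rec)
  res_all <- all_pairs_sync(pre, pairs = "all", trim = 0.2)
  res_adj <- all_pairs_sync(pre, pairs = "adjacent", trim = 0.2)
  expect_equal(nrow(res_all), 2 * choose(6, 2))
  expect_equal(nrow(res_adj), 2 * 5)
  # invariants: plv = |V| in [0, 1], ac in [-1, 1]
  expect_true(all(res_all$plv >= 0 & res_all$plv <= 1))
  expect_true(all(abs(abs(res_all$V) - res_all$plv) < 1e-12))
  expect_true(all(abs(res_all$ac) <= 1))
  # swap symmetry: computing (m, n) by relabelling negates theta only
  ml <- pre$ml
  phi1 <- instantaneous_phase(ml[, 1]); phi2 <- instantaneous_phase(ml[, 2])
  v12 <- complex_sync(phi1, phi2); v21 <- complex_sync(phi2, phi1)
  expect_equal(v21, Conj(v12), tolerance = 1e-12)
  # bad pair matrices are refused
  expect_error(all_pairs_sync(pre, pairs = cbind(3, 2)), "n < m")
  expect_error(all_pairs_sync(pre, pairs = cbind(1, 9)), "n < m")
})

test_that("planted two-cluster structure orders within > cross pair V", {
  # small-scale planted-structure check over seeds (full scale is exercised
  # in the acceptance suite)
  ok <- vapply(1:10, function(sd) {
    spec <- small_cluster_spec(seed = 300 + sd, clusters = list(1:3, 4:6),
                               fs = 250, duration = 8)
    res <- all_pairs_sync(preprocess_recording(generate_recording(spec)),
                          pairs = "adjacent", trim = 0.5)
    within <- res$sensor_n != 3
    min(res$V[within]) > max(res$V[!within])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
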