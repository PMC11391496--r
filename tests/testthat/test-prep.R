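make_series <- function(M, tr = 1) new_vf_series(M, tr)

test_that("outlier detection flags the union of the two criteria", {
  Tn <- 100
  set.seed(1)
  S <- make_series(matrix(rnorm(5 * Tn), 5, Tn))
  motion <- matrix(0, Tn, 6)
  expect_false(any(detect_outlier_frames(make_series(matrix(1, 5, Tn)), motion)))

  # a global-signal spike only
  S2 <- unclass(S)
  S2[, 50] <- S2[, 50] + 10
  fl_z <- detect_outlier_frames(make_series(S2), motion, z_thresh = 5)
  expect_true(fl_z[50])
  expect_equal(sum(fl_z), 1)

  # a motion jump only
  motion2 <- motion
  motion2[70:Tn, 1] <- 2
  fl_m <- detect_outlier_frames(S, motion2, motion_thresh_mm = 0.9)
  expect_true(fl_m[70])
  expect_false(any(fl_m[-70]))

  # union of both criteria
  fl_both <- detect_outlier_frames(make_series(S2), motion2)
  expect_true(all(fl_both[c(50, 70)]))

  expect_error(detect_outlier_frames(S, motion[1:10, ]), "timepoints")
})

test_that("confound regression yields residuals orthogonal to confounds", {
  set.seed(2)
  Tn <- 120
  S <- make_series(matrix(rnorm(6 * Tn), 6, Tn))
  conf <- cbind(a = rnorm(Tn), b = rnorm(Tn), c = rnorm(Tn))
  res <- regress_confounds(S, conf)
  ip <- crossprod(t(unclass(res)) , conf) # regions x confounds inner products
  expect_lt(max(abs(ip)), 1e-8)
  expect_lt(max(abs(rowMeans(unclass(res)))), 1e-10)

  # intercept-only (empty confound set): output is the demeaned series
  res0 <- regress_confounds(S, matrix(0, Tn, 0))
  expect_equal(unclass(res0), unclass(S) - rowMeans(unclass(S)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("regression special cases behave", {
  set.seed(3)
  Tn <- 80
  x <- rnorm(Tn)
  S <- make_series(rbind(sig = x, noise = rnorm(Tn)))
  # series equal to a confound column: residual ~ 0
  res <- regress_confounds(S, cbind(x = x))
  expect_lt(max(abs(unclass(res)["sig", ])), 1e-10)
  # collinear columns dropped with a warning
  expect_warning(regress_confounds(S, cbind(a = x, b = 2 * x)), "collinear")
  # regression is idempotent
  conf <- cbind(a = rnorm(Tn), b = rnorm(Tn))
  r1 <- regress_confounds(S, conf)
  r2 <- regress_confounds(r1, conf)
  expect_lt(sqrt(mean((unclass(r1) - unclass(r2))^2)), 1e-8)
})

sin_gain <- function(freq, low = 0.009, high = 0.10, tr = 1, Tn = 600) {
  tt <- (seq_len(Tn) - 1) * tr
  x <- sin(2 * pi * freq * tt)
  y <- unclass(bandpass(make_series(rbind(x), tr), low, high))[1, ]
  core <- seq(round(Tn * 0.2), round(Tn * 0.8)) # avoid filter edge transients
  # amplitude via least squares on the known frequency (FFT-free oracle)
  B <- cbind(sin(2 * pi * freq * tt[core]), cos(2 * pi * freq * tt[core]))
  sqrt(sum(qr.coef(qr(B), y[core])^2))
}

test_that("band-pass keeps in-band and rejects out-of-band sinusoids", {
  expect_gt(sin_gain(0.05), 0.95)  # passband: within 5% of unit amplitude
  expect_lt(sin_gain(0.05), 1.05)
  expect_lt(sin_gain(0.2), 0.10)   # stopband
  # constant series -> DC removed
  flat <- bandpass(make_series(matrix(5, 2, 400), 1))
  expect_lt(max(abs(unclass(flat))), 0.2)
  expect_error(bandpass(make_series(matrix(rnorm(100), 1), 1), 0.009, 0.6),
               "Nyquist")
  expect_error(bandpass(make_series(matrix(rnorm(100), 1), 1), 0.2, 0.1))
})

test_that("filtering commutes with region permutation and prep sets provenance", {
  set.seed(4)
  S <- make_series(matrix(rnorm(4 * 200), 4, 200,
                          dimnames = list(letters[1:4], NULL)))
  f <- bandpass(S)
  perm <- c(3, 1, 4, 2)
  f_perm <- bandpass(make_series(unclass(S)[perm, ], 1))
  expect_equal(unclass(f)[perm, ], unclass(f_perm), ignore_attr = TRUE)

  motion <- matrix(rnorm(200 * 6, sd = 0.01), 200, 6)
  p <- prep_series(S, motion, design = make_design(1, 100, 100, 1))
  expect_true(attr(p, "prepped"))
})
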