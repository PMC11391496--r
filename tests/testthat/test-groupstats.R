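sim_groups <- function(n = c(10, 12, 11), shift = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  g <- rep(c("A", "B", "C"), times = n)
  y <- rnorm(sum(n)) + rep(shift, times = n)
  list(y = y, g = g,
       cov = data.frame(age = rnorm(sum(n), 30, 5),
                        sex01 = rbinom(sum(n), 1, 0.5)))
}

test_that("covariate-free ANCOVA equals the one-way ANOVA oracle", {
  d <- sim_groups(seed = 2)
  res <- ancova(d$y, d$g)
  oracle <- summary(aov(d$y ~ factor(d$g)))[[1]]
  expect_equal(res$F, oracle$`F value`[1], tolerance = 1e-8)
  expect_equal(res$p, oracle$`Pr(>F)`[1], tolerance = 1e-8)
  expect_equal(res$df1, oracle$Df[1])
  # with covariates, matches lm + model comparison
  res_c <- ancova(d$y, d$g, d$cov)
  full <- lm(d$y ~ age + sex01 + factor(d$g), data = d$cov)
  red <- lm(d$y ~ age + sex01, data = d$cov)
  an <- anova(red, full)
  expect_equal(res_c$F, an$F[2], tolerance = 1e-8)
  expect_equal(res_c$p, an$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("adjusted means equal lm predictions at the covariate means", {
  d <- sim_groups(shift = c(0, 1, 2), seed = 3)
  res <- ancova(d$y, d$g, d$cov)
  df <- data.frame(y = d$y, g = factor(d$g), d$cov)
  fit <- lm(y ~ age + sex01 + g, data = df)
  oracle <- predict(fit, newdata = data.frame(
    age = mean(d$cov$age), sex01 = mean(d$cov$sex01),
    g = factor(c("A", "B", "C"))
  ))
  expect_equal(unname(res$adjusted_means), unname(oracle), tolerance = 1e-10)
})

test_that("degenerate features report F = 0, p = 1", {
  d <- sim_groups()
  res <- ancova(rep(3.2, length(d$g)), d$g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_error(ancova(d$y[1:3], c("A", "A", "B")), "n >= 2")
})

test_that("pairwise contrasts reduce to the omnibus for two groups", {
  set.seed(4)
  y <- rnorm(24)
  g <- rep(c("A", "B"), each = 12)
  cov <- data.frame(age = rnorm(24))
  om <- ancova(y, g, cov)
  pw <- posthoc_pairwise(y, g, cov)
  expect_equal(pw$t^2, om$F, tolerance = 1e-10) # F = t^2
  expect_equal(pw$p, om$p, tolerance = 1e-10)
  # swapping the pair flips the sign, same p
  pw_rev <- posthoc_pairwise(y, g, cov, pairs = list(c("B", "A")))
  expect_equal(pw_rev$diff, -pw$diff)
  expect_equal(pw_rev$p, pw$p)
  expect_error(posthoc_pairwise(y, g, cov, pairs = list(c("A", "Z"))),
               "unknown group pair")
})

test_that("a 2-SD shift at n = 30 is detected with high power", {
  hits <- 0
  for (s in 1:25) {
    set.seed(500 + s)
    y <- c(rnorm(30), rnorm(30, mean = 2))
    g <- rep(c("A", "B"), each = 30)
    pw <- posthoc_pairwise(y, g)
    if (pw$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.95)
})

test_that("null ANCOVA rejection rate is calibrated at alpha = 0.05", {
  set.seed(6)
  reps <- 2000
  p <- numeric(reps)
  g <- rep(c("A", "B", "C"), times = c(10, 10, 10))
  for (i in seq_len(reps)) {
    cov <- data.frame(age = rnorm(30))
    p[i] <- ancova(rnorm(30), g, cov)$p
  }
  expect_gt(mean(p < 0.05), 0.04)
  expect_lt(mean(p < 0.05), 0.06)
})

test_that("BH FDR matches the step-up enumeration", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(sum(r$reject), 3) # 0.03 <= 3/4 * 0.05
  expect_equal(r$q, p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"))
  expect_true(all(r$q >= r$p))
  r1 <- fdr_bh(1)
  expect_false(r1$reject)
  expect_equal(fdr_bh(rep(1, 5))$q, rep(1, 5))
  single <- fdr_bh(0.04)
  expect_true(single$reject)
  expect_equal(single$q, 0.04)
  expect_equal(nrow(fdr_bh(numeric(0))), 0)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("HC standardization gives mean-0 SD-1 reference scores", {
  set.seed(7)
  x <- c(rnorm(20, 10, 2), rnorm(30, 8, 3))
  ref <- seq_len(20)
  z <- standardize_scores(x, ref)
  expect_equal(mean(z[ref]), 0, tolerance = 1e-12)
  expect_equal(sd(z[ref]), 1, tolerance = 1e-12)
  # a reference subject exactly at the reference mean maps to 0
  z0 <- standardize_scores(c(x[ref], mean(x[ref])), c(ref, 21L))
  expect_equal(z0[21], 0, tolerance = 1e-12)
  # a value one reference SD above the reference mean maps to 1
  z1 <- standardize_scores(c(x, mean(x[ref]) + sd(x[ref])), ref)
  expect_equal(z1[length(z1)], 1, tolerance = 1e-12)
  expect_error(standardize_scores(rep(2, 10), 1:5), "SD is zero")
})

test_that("partial correlation matches the closed-form single-covariate formula", {
  set.seed(8)
  n <- 200
  z <- rnorm(n)
  x <- 0.7 * z + rnorm(n)
  y <- 0.5 * z + rnorm(n)
  pc <- partial_correlation(x, y, data.frame(z = z))
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pc$r, closed, tolerance = 1e-10)
  # no covariates: plain Pearson
  pc0 <- partial_correlation(x, y)
  expect_equal(pc0$r, rxy, tolerance = 1e-12)
  expect_equal(pc0$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  # shared-covariate-only association vanishes after adjustment
  set.seed(9)
  n <- 500
  z <- rnorm(n)
  x2 <- z + rnorm(n)
  y2 <- z + rnorm(n)
  expect_lt(abs(partial_correlation(x2, y2, data.frame(z = z))$r), 0.1)
  expect_error(partial_correlation(1:4, 1:4, data.frame(z = rnorm(4))), "n >")
})

test_that("group_compare runs families with FDR and selective post hoc", {
  set.seed(10)
  n <- c(15, 15, 15)
  g <- rep(c("A", "B", "C"), times = n)
  Y <- matrix(rnorm(45 * 20), 45, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  Y[, 1] <- Y[, 1] + (g == "B") * 3 # one real effect
  cov <- data.frame(age = rnorm(45))
  res <- group_compare(Y, g, cov, alpha = 0.05)
  expect_true(res$omnibus$reject[1])
  expect_equal(res$omnibus$q, p.adjust(res$omnibus$p, "BH"))
  expect_true(all(res$pairwise$feature %in%
                    res$omnibus$feature[res$omnibus$reject]))
  # vectorized omnibus equals per-feature ancova
  a1 <- ancova(Y[, 1], g, cov)
  expect_equal(res$omnibus$F[1], a1$F, tolerance = 1e-10)
  res_none <- group_compare(Y, g, cov, posthoc = "none")
  expect_null(res_none$pairwise)
})
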