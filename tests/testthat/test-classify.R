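make_shift_data <- function(n = 60, p_noise = 9, shift = 3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * (p_noise + 1)), n)
  colnames(X) <- c("signal", paste0("noise", seq_len(p_noise)))
  X[, "signal"] <- X[, "signal"] + (y == "b") * shift
  list(X = as.data.frame(X), y = y)
}

test_that("stepwise selection finds the informative feature first", {
  first_hits <- 0
  n_sets <- 20
  for (s in seq_len(n_sets)) {
    d <- make_shift_data(seed = 100 + s)
    sw <- forward_stepwise_logistic(d$X, d$y)
    if (length(sw$selected) && sw$selected[1] == "signal") {
      first_hits <- first_hits + 1
    }
  }
  expect_gte(first_hits / n_sets, 0.95)
})

test_that("stepwise selection path is deterministic and recorded", {
  d <- make_shift_data(seed = 5)
  sw1 <- forward_stepwise_logistic(d$X, d$y)
  sw2 <- forward_stepwise_logistic(d$X, d$y)
  expect_identical(sw1$selected, sw2$selected)
  expect_identical(sw1$steps, sw2$steps)
  expect_true(all(sw1$steps$p < 0.05)) # every entrant met the criterion
  expect_equal(sw1$steps$feature, sw1$selected)
  expect_error(forward_stepwise_logistic(d$X, rep("a", 60)), "2 classes")
})

test_that("null features rarely enter the model", {
  enters <- 0
  n_sets <- 40
  for (s in seq_len(n_sets)) {
    d <- make_shift_data(shift = 0, seed = 200 + s)
    sw <- forward_stepwise_logistic(d$X, d$y)
    if (length(sw$selected) >= 1) enters <- enters + 1
  }
  # 10 candidates at p_enter 0.05: per-dataset entry probability roughly
  # 1 - 0.95^10 ~ 0.40; allow a generous Monte-Carlo band
  expect_lt(enters / n_sets, 0.65)
})

test_that("perfect separation is detected and flagged", {
  y <- factor(rep(c("a", "b"), each = 10))
  X <- data.frame(x = c(rnorm(10, -5), rnorm(10, 5)))
  sw <- forward_stepwise_logistic(X, y)
  expect_equal(sw$selected, "x")
  expect_true(sw$separation)
  expect_true(all(is.finite(sw$coefficients)))
})

test_that("the network learns linearly separable data to high accuracy", {
  set.seed(20)
  n <- 80
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- data.frame(x1 = rnorm(n) + (y == "b") * 4,
                  x2 = rnorm(n) - (y == "b") * 4)
  net <- train_nn(X, y, hidden = 4, seed = 3)
  acc <- mean((predict(net, X) > 0.5) == (y == "b"))
  expect_gte(acc, 0.99)
  # determinism
  net2 <- train_nn(X, y, hidden = 4, seed = 3)
  expect_identical(net$weights, net2$weights)
  expect_warning(train_nn(X, y, init_offset = 0, max_iter = 5, seed = 1),
                 "symmetry")
})

test_that("rank AUC equals the Mann-Whitney U oracle, ties at 1/2", {
  y <- factor(c("a", "a", "b", "b"))
  expect_equal(roc_auc(c(1, 2, 3, 4), y), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), y), 0)
  expect_equal(roc_auc(c(1, 1, 1, 1), y), 0.5)
  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    s <- c(rnorm(n0), rnorm(n1, 0.5))
    yy <- factor(rep(c("a", "b"), c(n0, n1)))
    u <- wilcox.test(s[yy == "b"], s[yy == "a"], exact = FALSE)$statistic
    expect_equal(roc_auc(s, yy), unname(u) / (n1 * n0), tolerance = 1e-12)
  }
  # invariance under strictly increasing transforms
  s <- rnorm(30)
  yy <- factor(rep(c("a", "b"), 15))
  expect_equal(roc_auc(s, yy), roc_auc(exp(s), yy))
  expect_error(roc_auc(1:3, factor(c("a", "a", "a"))), "2 classes")
})

test_that("repeated splits: separation gives AUC 1, single rep collapses CI", {
  set.seed(30)
  y <- factor(rep(c("a", "b"), each = 20))
  X <- data.frame(x = c(rnorm(20), rnorm(20) + 10)) # fully separated classes
  ev <- evaluate_repeated_split(X, y, model = "logistic",
                                repetitions = 10, master_seed = 1)
  expect_true(all(ev$auc == 1))
  d <- make_shift_data(n = 40, shift = 8, seed = 30)
  ev1 <- evaluate_repeated_split(d$X, d$y, model = "logistic",
                                 repetitions = 1, master_seed = 2)
  expect_equal(ev1$ci95, c(ev1$auc, ev1$auc))
  # determinism of the whole evaluation
  ev2 <- evaluate_repeated_split(X, y, model = "logistic",
                                 repetitions = 10, master_seed = 1)
  expect_identical(ev$auc, ev2$auc)
})

test_that("feature selection happens strictly inside each training split", {
  d <- make_shift_data(n = 40, shift = 2, seed = 31)
  ev <- evaluate_repeated_split(d$X, d$y, model = "stepwise_nn",
                                repetitions = 5, master_seed = 9)
  for (det in ev$details) {
    sw <- forward_stepwise_logistic(d$X[det$train_index, ],
                                    d$y[det$train_index])
    expect_identical(det$selected, sw$selected) # reproducible from train rows only
  }
})
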