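# Patient-subgroup classification: forward-stepwise logistic feature
# selection, a single-hidden-layer feed-forward network trained by
# scaled conjugate gradient, repeated stratified 70/30 evaluation, and
# rank-based ROC AUC.

as_binary_labels <- function(labels, min_per_class = 2) {
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly 2 classes", call. = FALSE)
  if (min(table(f)) < min_per_class) {
    stop(sprintf("need at least %d subject(s) per class", min_per_class),
         call. = FALSE)
  }
  f
}

#' Forward-stepwise logistic feature selection
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' feature with the smallest likelihood-ratio p value, stopping when no
#' remaining candidate enters at `p_enter`. Features are standardized
#' internally; maximum-likelihood fits use iteratively reweighted least
#' squares with convergence tolerance `1e-8` and an iteration cap of
#' 100. Perfect separation is detected (fitted probabilities numerically
#' 0/1 for every subject) and flagged; coefficients then come from the
#' last stable iteration of the capped fit.
#'
#' @param features data.frame / matrix, subjects x candidate features.
#' @param labels binary class labels (2-level factor or coercible).
#' @param p_enter entry threshold on the likelihood-ratio p (default
#'   0.05).
#' @return A list of class `vf_stepwise`: `selected` (ordered names),
#'   `steps` (data.frame feature, chisq, p per entry step),
#'   `coefficients` (final model, original feature scale suppressed:
#'   standardized scale), `separation` (flag), `converged`, `center`,
#'   `scale`.
#' @export
forward_stepwise_logistic <- function(features, labels, p_enter = 0.05) {
  y <- as_binary_labels(labels)
  yn <- as.numeric(y) - 1
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  fit_dev <- function(cols) {
    Xc <- cbind(`(Intercept)` = 1, Xs[, cols, drop = FALSE])
    f <- suppressWarnings(stats::glm.fit(Xc, yn, family = stats::binomial(),
                                         control = ctrl))
    f
  }
  null_fit <- fit_dev(character(0))
  selected <- character(0)
  steps <- list()
  dev_cur <- null_fit$deviance
  fit_cur <- null_fit
  candidates <- colnames(Xs)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trial <- vapply(remaining, function(f) fit_dev(c(selected, f))$deviance,
                    numeric(1))
    chisq <- pmax(dev_cur - trial, 0)
    pvals <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    best <- which.min(pvals)
    if (pvals[best] >= p_enter) break
    selected <- c(selected, remaining[best])
    steps[[length(steps) + 1L]] <- data.frame(
      feature = remaining[best], chisq = chisq[best], p = pvals[best],
      stringsAsFactors = FALSE
    )
    dev_cur <- trial[best]
    fit_cur <- fit_dev(selected)
  }
  fitted <- fit_cur$fitted.values
  separation <- length(selected) > 0 &&
    all(abs(fitted - yn) < 1e-6) && fit_cur$deviance < 1e-4
  structure(
    list(selected = selected,
         steps = if (length(steps)) do.call(rbind, steps) else
           data.frame(feature = character(0), chisq = numeric(0), p = numeric(0)),
         coefficients = fit_cur$coefficients,
         separation = separation,
         converged = fit_cur$converged %||% TRUE,
         center = ctr, scale = scl, p_enter = p_enter),
    class = "vf_stepwise"
  )
}

#' @export
print.vf_stepwise <- function(x, ...) {
  cat(sprintf("<vf_stepwise> %d feature(s) selected%s: %s\n",
              length(x$selected),
              if (x$separation) " [perfect separation]" else "",
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

# ---- single-hidden-layer network, scaled conjugate gradient ----------

nn_unpack <- function(w, d, H) {
  n1 <- (d + 1) * H
  list(W1 = matrix(w[seq_len(n1)], d + 1, H),
       W2 = matrix(w[-seq_len(n1)], H + 1, 2))
}

nn_forward <- function(w, X1, d, H) {
  wm <- nn_unpack(w, d, H)
  Z <- tanh(X1 %*% wm$W1)             # n x H
  A <- cbind(1, Z) %*% wm$W2          # n x 2 logits
  A <- A - apply(A, 1, max)
  P <- exp(A)
  P <- P / rowSums(P)
  list(Z = Z, P = P)
}

# cross-entropy loss and gradient for softmax output, tanh hidden
nn_loss_grad <- function(w, X1, Y, d, H) {
  fw <- nn_forward(w, X1, d, H)
  eps <- 1e-12
  loss <- -sum(Y * log(fw$P + eps))
  D2 <- fw$P - Y                       # n x 2
  Z1 <- cbind(1, fw$Z)
  g2 <- t(Z1) %*% D2                   # (H+1) x 2
  Dh <- (D2 %*% t(nn_unpack(w, d, H)$W2[-1, , drop = FALSE])) * (1 - fw$Z^2)
  g1 <- t(X1) %*% Dh                   # (d+1) x H
  list(loss = loss, grad = c(g1, g2))
}

# Moller's scaled conjugate gradient with the stated initial scaling
# parameters; returns the weight vector at convergence or iteration cap.
scg_optimize <- function(w, fn, lambda0 = 5e-7, sigma0 = 5e-5,
                         max_iter = 300, grad_tol = 1e-6) {
  ev <- fn(w)
  r <- -ev$grad
  p <- r
  lambda <- lambda0
  lambda_bar <- 0
  success <- TRUE
  nw <- length(w)
  delta <- 0
  for (k in seq_len(max_iter)) {
    p2 <- sum(p^2)
    if (sqrt(sum(r^2)) < grad_tol || p2 < 1e-30) break
    if (success) {
      sigma_k <- sigma0 / sqrt(p2)
      g2 <- fn(w + sigma_k * p)$grad
      s <- (g2 - ev$grad) / sigma_k
      delta <- sum(p * s)
    }
    delta_k <- delta + (lambda - lambda_bar) * p2
    if (delta_k <= 0) {
      lambda_bar <- 2 * (lambda - delta_k / p2)
      delta_k <- -delta_k + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_k
    ev_new <- fn(w + alpha * p)
    Delta <- 2 * delta_k * (ev$loss - ev_new$loss) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      w <- w + alpha * p
      r_new <- -ev_new$grad
      lambda_bar <- 0
      success <- TRUE
      if (k %% nw == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      ev <- ev_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (is.finite(Delta) && Delta < 0.25) lambda <- lambda + delta_k * (1 - Delta) / p2
    if (!is.finite(ev$loss)) stop("non-finite loss in network training", call. = FALSE)
  }
  w
}

#' Train a single-hidden-layer feed-forward classifier
#'
#' Tanh hidden units and a two-class softmax output trained on
#' cross-entropy by scaled conjugate gradient with initial lambda
#' `5e-7` and initial sigma `5e-5`. Initial weights are drawn uniformly
#' from \[center - offset, center + offset\] (default \[-0.5, 0.5\]);
#' a zero offset leaves all hidden units identical (symmetric-weight
#' degeneracy) and is warned about. Inputs are standardized internally
#' using training statistics. Deterministic given `seed`.
#'
#' @param features subjects x features matrix / data.frame.
#' @param labels binary labels.
#' @param hidden number of hidden units (default 4).
#' @param lambda0,sigma0 initial SCG scaling parameters.
#' @param init_center,init_offset uniform weight-initialization interval
#'   parameters.
#' @param max_iter SCG iteration cap.
#' @param seed integer seed for the weight initialization.
#' @return A list of class `vf_nn` with the trained weights and the
#'   preprocessing statistics.
#' @export
train_nn <- function(features, labels, hidden = 4, lambda0 = 5e-7,
                     sigma0 = 5e-5, init_center = 0, init_offset = 0.5,
                     max_iter = 300, seed = 1L) {
  y <- as_binary_labels(labels)
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  X1 <- cbind(1, Xs)
  d <- ncol(Xs)
  Y <- stats::model.matrix(~ y - 1)
  if (init_offset == 0) {
    warning("init_offset = 0: all hidden units start identical (symmetry is never broken)",
            call. = FALSE)
  }
  nw <- (d + 1) * hidden + (hidden + 1) * 2
  w0 <- with_local_seed(seed, stats::runif(nw, init_center - init_offset,
                                           init_center + init_offset))
  fn <- function(w) nn_loss_grad(w, X1, Y, d, hidden)
  w <- scg_optimize(w0, fn, lambda0 = lambda0, sigma0 = sigma0,
                    max_iter = max_iter)
  structure(
    list(weights = w, hidden = hidden, d = d, center = ctr, scale = scl,
         levels = levels(y), feature_names = colnames(X)),
    class = "vf_nn"
  )
}

#' Predict class probabilities from a trained network
#'
#' @param object a `vf_nn` from [train_nn()].
#' @param newdata subjects x features table with the training columns.
#' @param ... unused.
#' @return Numeric vector: probability of the second class level.
#' @export
predict.vf_nn <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  Xs <- scale(X, center = object$center, scale = object$scale)
  fw <- nn_forward(object$weights, cbind(1, Xs), object$d, object$hidden)
  fw$P[, 2]
}

#' Rank-based ROC area under the curve
#'
#' Equals the Mann-Whitney U statistic divided by `n1 * n0`; tied scores
#' contribute 1/2.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels; the second factor level is "positive".
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as_binary_labels(labels, min_per_class = 1)) - 1L
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified split evaluation
#'
#' Per repetition: a stratified train/test split (default 70/30), model
#' fitting strictly inside the training subset (feature selection
#' included), and test-set AUC. Summarized by the mean AUC and a
#' percentile 95% interval.
#'
#' @param features subjects x features table.
#' @param labels binary labels.
#' @param model `"stepwise_nn"` (forward-stepwise logistic selection on
#'   the training split, then the neural network on the selected
#'   features; repetitions whose selection is empty fall back to the
#'   stepwise logistic scores of the best candidate-free model, i.e.
#'   constant scores), `"logistic"` (plain logistic on all features), or
#'   `"nn"` (network on all features).
#' @param train_frac training fraction (default 0.7).
#' @param repetitions number of repeated splits (default 100).
#' @param master_seed master seed; per-repetition seeds derive from it.
#' @param p_enter stepwise entry threshold.
#' @param hidden hidden units for the network.
#' @return A list of class `vf_split_eval`: `auc` (per repetition),
#'   `mean_auc`, `ci95` (percentile interval), `details` (per-rep list
#'   with `train_index`, `selected`, `seed`).
#' @export
evaluate_repeated_split <- function(features, labels,
                                    model = c("stepwise_nn", "logistic", "nn"),
                                    train_frac = 0.7, repetitions = 100,
                                    master_seed = 1L, p_enter = 0.05,
                                    hidden = 4) {
  model <- match.arg(model)
  y <- as_binary_labels(labels)
  X <- as.data.frame(features)
  n <- length(y)
  aucs <- numeric(repetitions)
  details <- vector("list", repetitions)
  for (rep_i in seq_len(repetitions)) {
    seed_r <- derive_seed(master_seed, rep_i, salt = 4L)
    train_idx <- with_local_seed(seed_r, {
      unlist(lapply(levels(y), function(lv) {
        idx <- which(y == lv)
        sample(idx, max(1, round(train_frac * length(idx))))
      }))
    })
    test_idx <- setdiff(seq_len(n), train_idx)
    # stratified sampling guarantees both classes in train; guard test
    if (length(unique(y[test_idx])) < 2) {
      stop("a split left one class out of the test set; lower train_frac",
           call. = FALSE)
    }
    sel <- NULL
    scores <- switch(
      model,
      stepwise_nn = {
        sw <- forward_stepwise_logistic(X[train_idx, , drop = FALSE],
                                        y[train_idx], p_enter = p_enter)
        sel <- sw$selected
        if (length(sel) == 0) {
          rep(0.5, length(test_idx))
        } else {
          net <- train_nn(X[train_idx, sel, drop = FALSE], y[train_idx],
                          hidden = hidden, seed = derive_seed(seed_r, 1L, salt = 5L))
          predict(net, X[test_idx, sel, drop = FALSE])
        }
      },
      logistic = {
        df_tr <- data.frame(.y = y[train_idx], X[train_idx, , drop = FALSE])
        fit <- suppressWarnings(stats::glm(.y ~ ., data = df_tr,
                                           family = stats::binomial()))
        suppressWarnings(stats::predict(fit, newdata = X[test_idx, , drop = FALSE],
                                        type = "response"))
      },
      nn = {
        net <- train_nn(X[train_idx, , drop = FALSE], y[train_idx],
                        hidden = hidden, seed = derive_seed(seed_r, 1L, salt = 5L))
        predict(net, X[test_idx, , drop = FALSE])
      }
    )
    aucs[rep_i] <- roc_auc(scores, y[test_idx])
    details[[rep_i]] <- list(train_index = sort(train_idx), selected = sel,
                             seed = seed_r)
  }
  ci <- if (repetitions > 1) unname(stats::quantile(aucs, c(0.025, 0.975))) else
    c(aucs, aucs)
  structure(list(auc = aucs, mean_auc = mean(aucs), ci95 = ci,
                 repetitions = repetitions, model = model, details = details),
            class = "vf_split_eval")
}

#' @export
print.vf_split_eval <- function(x, ...) {
  cat(sprintf("<vf_split_eval> %s, %d repetitions: mean AUC %.3f [%.3f, %.3f]\n",
              x$model, x$repetitions, x$mean_auc, x$ci95[1], x$ci95[2]))
  invisible(x)
}
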