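# Covariate-adjusted group statistics: ANCOVA omnibus F, post hoc
# pairwise contrasts of adjusted means, Benjamini-Hochberg FDR,
# HC-standardization of behavioural scores, and partial correlation.

# Build the [intercept | covariates] and [intercept | covariates | group]
# design matrices, dropping collinear covariate columns with a warning.
build_group_designs <- function(groups, covariates = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  n <- length(groups)
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(covariates)
    if (!is.numeric(cv)) stop("covariates must be numeric (encode sex as 0/1)", call. = FALSE)
    X0 <- cbind(X0, cv)
    q0 <- qr(X0)
    if (q0$rank < ncol(X0)) {
      drop_idx <- q0$pivot[seq.int(q0$rank + 1L, ncol(X0))]
      warning(sprintf("dropping collinear covariate column(s): %s",
                      paste(colnames(X0)[drop_idx], collapse = ", ")), call. = FALSE)
      X0 <- X0[, -drop_idx, drop = FALSE]
    }
  }
  G <- stats::model.matrix(~groups)[, -1, drop = FALSE]
  colnames(G) <- paste0("group", levels(groups)[-1])
  list(X0 = X0, X1 = cbind(X0, G), groups = groups)
}

#' One-way ANCOVA omnibus test for a per-subject feature
#'
#' Linear model `feature ~ covariates + group`; the F statistic tests
#' the group block (full vs covariates-only model). With no covariates
#' this is exactly one-way ANOVA. A feature with zero residual and zero
#' group variation (e.g. identical across subjects) is reported as
#' `F = 0, p = 1` by convention.
#'
#' @param feature numeric vector, one value per subject.
#' @param groups group labels (factor or character).
#' @param covariates numeric matrix / data.frame of covariates (sex must
#'   be encoded as a 0/1 indicator), or `NULL`.
#' @return A list: `F`, `p`, `df1`, `df2`, `adjusted_means` (per-group
#'   means at the covariate grand means), `n`.
#' @export
ancova <- function(feature, groups, covariates = NULL) {
  d <- build_group_designs(groups, covariates)
  n <- length(feature)
  stopifnot(length(d$groups) == n)
  if (any(table(d$groups) < 2)) stop("every group needs n >= 2", call. = FALSE)
  q0 <- qr(d$X0); q1 <- qr(d$X1)
  rss0 <- sum(qr.resid(q0, feature)^2)
  rss1 <- sum(qr.resid(q1, feature)^2)
  df1 <- ncol(d$X1) - ncol(d$X0)
  df2 <- n - ncol(d$X1)
  tol <- 1e-12 * (sum(feature^2) + 1)
  if (rss1 <= tol && rss0 - rss1 <= tol) {
    Fst <- 0; p <- 1 # degenerate: no variation anywhere
  } else {
    Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  }
  beta <- qr.coef(q1, feature)
  # adjusted means: prediction at each group with covariates at grand mean
  x_cov <- colMeans(d$X0) # intercept + covariate means
  lev <- levels(d$groups)
  adj <- vapply(lev, function(g) {
    gvec <- as.numeric(lev[-1] == g)
    sum(c(x_cov, gvec) * beta)
  }, numeric(1))
  list(F = Fst, p = p, df1 = df1, df2 = df2, adjusted_means = adj, n = n)
}

#' Post hoc pairwise contrasts of covariate-adjusted means
#'
#' Contrasts between group levels from the full ANCOVA model: the
#' adjusted mean difference, its t statistic on the residual degrees of
#' freedom, and a two-sided p value.
#'
#' @inheritParams ancova
#' @param pairs list of 2-element character vectors naming the group
#'   pairs; default all unordered pairs.
#' @return data.frame with columns `a`, `b`, `diff` (adjusted mean of
#'   `a` minus `b`), `t`, `p`, `df`.
#' @export
posthoc_pairwise <- function(feature, groups, covariates = NULL, pairs = NULL) {
  d <- build_group_designs(groups, covariates)
  lev <- levels(d$groups)
  if (is.null(pairs)) {
    pairs <- utils::combn(lev, 2, simplify = FALSE)
  }
  for (pr in pairs) {
    if (!all(pr %in% lev)) {
      stop(sprintf("unknown group pair (%s); groups are: %s",
                   paste(pr, collapse = ", "), paste(lev, collapse = ", ")),
           call. = FALSE)
    }
  }
  q1 <- qr(d$X1)
  n <- length(feature)
  p1 <- ncol(d$X1)
  beta <- qr.coef(q1, feature)
  df <- n - p1
  sigma2 <- sum(qr.resid(q1, feature)^2) / df
  XtX_inv <- chol2inv(qr.R(q1))
  # contrast vector for "group a minus group b" touches only the group
  # dummy columns (covariates cancel)
  gcols <- seq.int(p1 - (length(lev) - 1) + 1, p1)
  out <- lapply(pairs, function(pr) {
    cv <- numeric(p1)
    ia <- match(pr[1], lev[-1]); ib <- match(pr[2], lev[-1])
    if (!is.na(ia)) cv[gcols[ia]] <- 1
    if (!is.na(ib)) cv[gcols[ib]] <- -1
    diff <- sum(cv * beta)
    se <- sqrt(sigma2 * drop(t(cv) %*% XtX_inv %*% cv))
    tval <- if (se > 0) diff / se else 0
    data.frame(a = pr[1], b = pr[2], diff = diff, t = tval,
               p = if (se > 0) 2 * stats::pt(-abs(tval), df) else 1,
               df = df, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up adjusted p values (via [stats::p.adjust()]) and rejection
#' flags at level `alpha` (`q < alpha`).
#'
#' @param pvalues numeric vector of p values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return data.frame with columns `p`, `q`, `reject` (empty input gives
#'   an empty frame).
#' @export
fdr_bh <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) {
    return(data.frame(p = numeric(0), q = numeric(0), reject = logical(0)))
  }
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, q = q, reject = q < alpha)
}

#' Standardize scores against a healthy-control reference
#'
#' `z = (x - mean_ref) / sd_ref`, with the reference mean and SD
#' (denominator n - 1) computed over the reference subjects only.
#'
#' @param scores numeric vector over all subjects.
#' @param reference logical mask or integer indices of the reference
#'   (HC) subjects.
#' @return z scores for every subject.
#' @export
standardize_scores <- function(scores, reference) {
  ref <- scores[reference]
  if (length(ref) < 2) stop("need at least 2 reference subjects", call. = FALSE)
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) stop("reference SD is zero", call. = FALSE)
  (scores - mean(ref)) / s
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on
#' \[intercept | covariates\]; the p value uses a t reference with
#' `n - 2 - k` degrees of freedom for `k` covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix / data.frame, or `NULL` (plain
#'   Pearson correlation).
#' @return A list: `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n <= k + 3) stop("need n > number of covariates + 3", call. = FALSE)
  if (k > 0) {
    X <- cbind(1, as.matrix(covariates))
    qx <- qr(X)
    x <- qr.resid(qx, x)
    y <- qr.resid(qx, y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate residuals: zero variance after covariate adjustment", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df, n = n)
}

#' Mass-univariate ANCOVA over a feature family with FDR
#'
#' Runs the covariate-adjusted omnibus test on every column of a feature
#' matrix, applies Benjamini-Hochberg across the family, and (by
#' default) computes post hoc pairwise contrasts only for features whose
#' omnibus test survives FDR. All features share the same design, so the
#' QR decompositions are computed once.
#'
#' @param features numeric matrix / data.frame, subjects x features.
#' @param groups group labels.
#' @param covariates numeric covariate table or `NULL`.
#' @param alpha FDR level for the family (default 0.05).
#' @param posthoc `"significant"` (default: pairwise tests only where
#'   the omnibus survives FDR), `"all"`, or `"none"`.
#' @return A list of class `vf_grouptest`: `omnibus` (data.frame
#'   feature, F, p, q, reject), `pairwise` (data.frame feature, a, b,
#'   diff, t, p, q), `alpha`.
#' @export
group_compare <- function(features, groups, covariates = NULL, alpha = 0.05,
                          posthoc = c("significant", "all", "none")) {
  posthoc <- match.arg(posthoc)
  Y <- as.matrix(features)
  d <- build_group_designs(groups, covariates)
  q0 <- qr(d$X0); q1 <- qr(d$X1)
  n <- nrow(Y)
  df1 <- ncol(d$X1) - ncol(d$X0)
  df2 <- n - ncol(d$X1)
  rss0 <- colSums(qr.resid(q0, Y)^2)
  rss1 <- colSums(qr.resid(q1, Y)^2)
  Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
  tol <- 1e-12 * (colSums(Y^2) + 1)
  degen <- rss1 <= tol & (rss0 - rss1) <= tol
  Fst[degen] <- 0
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  p[degen] <- 1
  adj <- fdr_bh(p, alpha)
  omnibus <- data.frame(
    feature = colnames(Y) %||% as.character(seq_len(ncol(Y))),
    F = unname(Fst), p = unname(p), q = adj$q, reject = adj$reject,
    stringsAsFactors = FALSE
  )
  pairwise <- NULL
  if (posthoc != "none") {
    which_feat <- if (posthoc == "significant") which(omnibus$reject) else seq_len(ncol(Y))
    if (length(which_feat)) {
      pw <- lapply(which_feat, function(j) {
        res <- posthoc_pairwise(Y[, j], d$groups, covariates)
        cbind(feature = omnibus$feature[j], res, stringsAsFactors = FALSE)
      })
      pairwise <- do.call(rbind, pw)
      pairwise$q <- stats::p.adjust(pairwise$p, method = "BH")
    }
  }
  structure(list(omnibus = omnibus, pairwise = pairwise, alpha = alpha),
            class = "vf_grouptest")
}

#' @export
print.vf_grouptest <- function(x, ...) {
  cat(sprintf("<vf_grouptest> %d features, %d FDR-significant at alpha = %g\n",
              nrow(x$omnibus), sum(x$omnibus$reject), x$alpha))
  invisible(x)
}
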