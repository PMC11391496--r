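# ROI-level block-design GLM (activation analogue) and laterality index
# with dominance classes.

#' Fit the block-design GLM to every region
#'
#' Ordinary least squares of each region's time series on the design
#' matrix; returns the task-regressor estimate with its t statistic
#' (beta / SE on residual degrees of freedom) and two-sided p value.
#'
#' @param series a `vf_series` (regions x timepoints).
#' @param design_mat design matrix from [design_matrix()] (must contain
#'   a `task` column and be full column rank).
#' @return data.frame with columns `region`, `beta`, `se`, `t`, `p`,
#'   `df`.
#' @export
fit_glm <- function(series, design_mat) {
  Tn <- ncol(series)
  X <- as.matrix(design_mat)
  if (nrow(X) != Tn) stop("design matrix row count must equal timepoints", call. = FALSE)
  if (!"task" %in% colnames(X)) stop("design matrix must contain a 'task' column", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  Y <- t(unclass(series))
  B <- qr.coef(qr_x, Y)
  E <- qr.resid(qr_x, Y)
  df <- Tn - ncol(X)
  sigma2 <- colSums(E^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  task_ix <- match("task", colnames(X))
  se <- sqrt(sigma2 * XtX_inv[task_ix, task_ix])
  beta <- B[task_ix, ]
  tval <- ifelse(se > 0, beta / se, 0)
  data.frame(
    region = rownames(series) %||% as.character(seq_len(nrow(series))),
    beta = unname(beta), se = unname(se), t = unname(tval),
    p = unname(2 * stats::pt(-abs(tval), df)), df = df,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Laterality index over a masked cortex
#'
#' `LI = (L - R) / (L + R)`, where L and R sum the suprathreshold
#' positive t mass (`t > threshold`) over left- and right-hemisphere
#' regions of the masked cortex. Dominance follows the +/-0.2 rule:
#' left-dominant when LI > 0.2, right-dominant when LI < -0.2, otherwise
#' bilateral. When no mass survives on either side the index is
#' undefined: dominance is reported as bilateral with `degenerate =
#' TRUE`.
#'
#' @param tvalues named per-region t values (names = region names), e.g.
#'   from [fit_glm()].
#' @param regions region table with `name`, `hemisphere`, `cortex`.
#' @param mask_cortex cortex-label prefix defining the mask; both
#'   hemispheres are included by matching `<hemi>-<mask_cortex>` labels
#'   (default `"frontal"`).
#' @param threshold t threshold above which mass counts (default 2).
#' @return A list: `li`, `dominance`, `left_mass`, `right_mass`,
#'   `degenerate`.
#' @export
laterality_index <- function(tvalues, regions, mask_cortex = "frontal",
                             threshold = 2) {
  left_lab <- paste0("left-", mask_cortex)
  right_lab <- paste0("right-", mask_cortex)
  lregs <- regions$name[regions$cortex == left_lab]
  rregs <- regions$name[regions$cortex == right_lab]
  if (!length(lregs) || !length(rregs)) {
    stop(sprintf("mask '%s' must cover both hemispheres", mask_cortex), call. = FALSE)
  }
  mass <- function(rr) {
    v <- tvalues[rr]
    v <- v[!is.na(v) & v > threshold]
    sum(v)
  }
  L <- mass(lregs)
  R <- mass(rregs)
  if (L + R == 0) {
    return(list(li = NA_real_, dominance = "bilateral",
                left_mass = L, right_mass = R, degenerate = TRUE))
  }
  li <- (L - R) / (L + R)
  dominance <- if (li > 0.2) "left" else if (li < -0.2) "right" else "bilateral"
  list(li = li, dominance = dominance, left_mass = L, right_mass = R,
       degenerate = FALSE)
}

#' Classify dominance from a laterality index
#'
#' @param li laterality index in \[-1, 1\].
#' @return `"left"` (LI > 0.2), `"right"` (LI < -0.2), else
#'   `"bilateral"`.
#' @export
dominance_class <- function(li) {
  ifelse(li > 0.2, "left", ifelse(li < -0.2, "right", "bilateral"))
}
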