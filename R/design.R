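# Block-design description and haemodynamic-response machinery shared by
# the cohort simulator, the denoising step, and the activation GLM.

#' Construct a rest/task block design
#'
#' Describes an alternating rest/task paradigm sampled at a fixed TR,
#' starting with a rest module. The default arguments reproduce a
#' five-block covert verbal-fluency paradigm with 30 s rest and 30 s
#' task modules at TR = 1 s (300 timepoints).
#'
#' @param n_blocks number of rest+task blocks.
#' @param rest_s rest-module duration in seconds.
#' @param task_s task-module duration in seconds.
#' @param tr_s repetition time (sampling interval) in seconds.
#' @return An object of class `vf_design`: a list with the block onsets
#'   (`onset_s`, `duration_s`, `condition`), `tr_s`, `n_timepoints`, and
#'   `total_s`.
#' @examples
#' d <- make_design()
#' d$n_timepoints # 300
#' @export
make_design <- function(n_blocks = 5, rest_s = 30, task_s = 30, tr_s = 1) {
  for (arg in c("n_blocks", "rest_s", "task_s", "tr_s")) {
    v <- get(arg)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", arg), call. = FALSE)
    }
  }
  n_blocks <- as.integer(n_blocks)
  total_s <- n_blocks * (rest_s + task_s)
  onsets <- data.frame(
    onset_s = as.vector(vapply(seq_len(n_blocks) - 1L, function(b) {
      c(b * (rest_s + task_s), b * (rest_s + task_s) + rest_s)
    }, numeric(2))),
    duration_s = rep(c(rest_s, task_s), n_blocks),
    condition = rep(c("rest", "task"), n_blocks),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      n_blocks = n_blocks, rest_s = rest_s, task_s = task_s, tr_s = tr_s,
      onsets = onsets, total_s = total_s,
      n_timepoints = as.integer(round(total_s / tr_s))
    ),
    class = "vf_design"
  )
}

#' @export
print.vf_design <- function(x, ...) {
  cat(sprintf(
    "<vf_design> %d blocks (%g s rest / %g s task), TR %g s, %d timepoints\n",
    x$n_blocks, x$rest_s, x$task_s, x$tr_s, x$n_timepoints
  ))
  invisible(x)
}

#' Canonical double-gamma haemodynamic response function
#'
#' The standard two-gamma impulse response: a positive lobe peaking near
#' 6 s minus an undershoot peaking near 16 s at 1/6 amplitude, scaled so
#' the peak equals 1.
#'
#' @param t time in seconds (vector).
#' @param peak_s,undershoot_s gamma shape parameters (unit rate), i.e.
#'   the modes of the positive and undershoot lobes.
#' @param ratio undershoot amplitude relative to the positive lobe.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak_s = 6, undershoot_s = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak_s, rate = 1) -
    stats::dgamma(t, shape = undershoot_s, rate = 1) / ratio
  ref <- seq(0, 32, by = 0.1)
  peak <- max(stats::dgamma(ref, shape = peak_s, rate = 1) -
                stats::dgamma(ref, shape = undershoot_s, rate = 1) / ratio)
  h / peak
}

#' Task regressor: boxcar convolved with the canonical HRF
#'
#' @param design a [make_design()] object.
#' @param derivative also return the temporal derivative column.
#' @return A matrix with `n_timepoints` rows and one column (`task`) or
#'   two (`task`, `task_deriv`).
#' @export
task_regressor <- function(design, derivative = FALSE) {
  stopifnot(inherits(design, "vf_design"))
  key <- sprintf("task_%d_%g_%g_%g_%d", design$n_blocks, design$rest_s,
                 design$task_s, design$tr_s, derivative)
  cached <- get0(key, envir = .vf_cache)
  if (!is.null(cached)) return(cached)
  tt <- (seq_len(design$n_timepoints) - 1) * design$tr_s
  box <- numeric(design$n_timepoints)
  task <- design$onsets[design$onsets$condition == "task", , drop = FALSE]
  for (i in seq_len(nrow(task))) {
    box[tt >= task$onset_s[i] & tt < task$onset_s[i] + task$duration_s[i]] <- 1
  }
  kern <- canonical_hrf(seq(0, 32, by = design$tr_s))
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_along(box)]
  conv <- conv / max(abs(conv))
  out <- cbind(task = conv)
  if (derivative) {
    d <- c(0, diff(conv)) / design$tr_s
    out <- cbind(out, task_deriv = d)
  }
  assign(key, out, envir = .vf_cache)
  out
}

#' GLM design matrix for the block paradigm
#'
#' Intercept, HRF-convolved task regressor, and low-order cosine drift
#' terms.
#'
#' @param design a [make_design()] object.
#' @param n_drift number of cosine drift regressors (default 2).
#' @return Matrix `n_timepoints` x regressors with column names
#'   `intercept`, `task`, `drift1`, ...
#' @export
design_matrix <- function(design, n_drift = 2) {
  Tn <- design$n_timepoints
  X <- cbind(intercept = rep(1, Tn), task_regressor(design))
  if (n_drift > 0) {
    tt <- seq_len(Tn) - 1
    drift <- vapply(seq_len(n_drift), function(k) {
      cos(pi * k * (tt + 0.5) / Tn)
    }, numeric(Tn))
    colnames(drift) <- paste0("drift", seq_len(n_drift))
    X <- cbind(X, drift)
  }
  X
}
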