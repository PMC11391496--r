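# Synthetic cohort generator. Emulates the data structure of a
# three-group verbal-fluency task-fMRI study: 132-region BOLD-like ROI
# time series with a planted correlation structure, group-specific
# connectivity perturbations on the left anterior inferior temporal
# gyrus, motion/nuisance confounds, covariates and behavioural scores.

#' Default 132-region parcellation table
#'
#' A synthetic analogue of a whole-brain atlas with 91 cortical, 15
#' subcortical and 26 cerebellar regions. Cortex labels partition the
#' regions; six left frontal/temporal regions (triIFG, operIFG, aMTG,
#' aITG, toMTG, toITG analogues) are flagged as ROIs.
#'
#' @return A data.frame with columns `name`, `hemisphere`
#'   (left/right/midline), `cortex`, and `is_roi` (logical).
#' @examples
#' r <- make_region_table()
#' nrow(r)          # 132
#' sum(r$is_roi)    # 6
#' @export
make_region_table <- function() {
  lf <- c("triIFG", "operIFG", "SFG", "MFG", "FP", "FOrb", "PreCG",
          "SMA", "FMC", "IFS", "MidFG", "SubCG", "CO", "FEF")          # 14
  lt <- c("aSTG", "pSTG", "aMTG", "pMTG", "toMTG", "aITG", "pITG",
          "toITG", "TP", "PT", "PP", "HG", "aTFusC", "pTFusC",
          "TOFusC", "pPaHC")                                           # 16
  lp <- c("PostCG", "SPL", "aSMG", "pSMG", "AG", "sLOC", "iLOC",
          "Precun", "Cuneal", "LG", "ICC", "SCC", "POC", "PCC", "OP")  # 15
  sc <- c("Thal", "Caud", "Put", "Pall", "Hipp", "Amyg", "Accu")       # 7 / side
  cb <- paste0("Cereb", 1:13)                                          # 13 / side
  reg <- function(names, hemi, cortex) {
    pre <- c(left = "L.", right = "R.", midline = "M.")[[hemi]]
    data.frame(name = paste0(pre, names), hemisphere = hemi,
               cortex = cortex, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    reg(lf, "left", "left-frontal"), reg(lf, "right", "right-frontal"),
    reg(lt, "left", "left-temporal"), reg(lt, "right", "right-temporal"),
    reg(lp, "left", "left-posterior"), reg(lp, "right", "right-posterior"),
    reg("MedPC", "midline", "midline-cortical"),
    reg(sc, "left", "subcortical"), reg(sc, "right", "subcortical"),
    reg("BStem", "midline", "subcortical"),
    reg(cb, "left", "cerebellar"), reg(cb, "right", "cerebellar")
  )
  tab$is_roi <- tab$name %in% paste0("L.", c("triIFG", "operIFG", "aMTG",
                                             "aITG", "toMTG", "toITG"))
  rownames(tab) <- NULL
  tab
}

#' Cohort-generation configuration
#'
#' Collects every knob of the synthetic cohort: group sizes, the planted
#' connectivity effect map, noise model, task amplitudes, covariate
#' distributions and the behavioural score model. Defaults emulate a
#' three-group design (29 HC / 30 TLE-HS / 28 TLE-NHS) in which the
#' TLE-HS-like group has reduced, and the TLE-NHS-like group enhanced,
#' connectivity between the left aITG analogue and the rest of the left
#' temporal cortex.
#'
#' @param group_sizes named integer vector of subjects per group.
#' @param effects named list (one entry per group) with elements
#'   `seed_region` (region name), `targets` (region names, or `NULL` for
#'   all other members of the seed region's cortex) and `offset`
#'   (additive correlation-scale shift on seed-target edges);
#'   `subject_sd` gives the SD of per-subject jitter around the group
#'   offset.
#' @param base_within,base_between baseline correlation inside / between
#'   cortex blocks.
#' @param noise list: `ar` (AR(1) coefficient of the latent signal),
#'   `obs_sd` (white observation noise SD), `drift_amp` (low-frequency
#'   drift amplitude), `drift_period_s` (drift period, seconds),
#'   `nuisance_load` (loading of the white-matter/CSF-like nuisance
#'   channels onto every region), `n_nuisance`, `motion_sd` (random-walk
#'   step SD of the six motion parameters), `outlier_prob` (per-frame
#'   probability of a global spike), `spike_amp` (spike amplitude, SD
#'   units).
#' @param task_amp list of per-cortex task response amplitudes (signal
#'   units per unit HRF): `left_frontal`, `right_frontal`,
#'   `left_temporal` (negative = task deactivation), `other`.
#' @param covariates list of covariate distribution parameters (means /
#'   SDs for age, education, MoCA per group; male proportion).
#' @param scores list: per-score `intercept`, `slope` (on the subject's
#'   generative seed-region mean connectivity) and common `sd`.
#' @param seed master seed; all per-subject randomness derives from it.
#' @return An object of class `vf_cohort_config`.
#' @export
cohort_config <- function(
    group_sizes = c("HC" = 29, "TLE-HS" = 30, "TLE-NHS" = 28),
    effects = list(
      "HC"      = list(seed_region = "L.aITG", targets = NULL, offset = 0),
      "TLE-HS"  = list(seed_region = "L.aITG", targets = NULL, offset = -0.25),
      "TLE-NHS" = list(seed_region = "L.aITG", targets = NULL, offset = 0.15),
      subject_sd = 0.05
    ),
    base_within = 0.4,
    base_between = 0.1,
    noise = list(ar = 0.3, obs_sd = 0.5, drift_amp = 0.5,
                 drift_period_s = 128, nuisance_load = 0.3, n_nuisance = 2,
                 motion_sd = 0.02, outlier_prob = 0.01, spike_amp = 6),
    task_amp = list(left_frontal = 0.8, right_frontal = 0.3,
                    left_temporal = -0.5, other = 0.1),
    covariates = list(
      age_mean = c("HC" = 28, "TLE-HS" = 29, "TLE-NHS" = 30), age_sd = 8,
      edu_mean = 12, edu_sd = 3,
      moca_mean = c("HC" = 28.5, "TLE-HS" = 26, "TLE-NHS" = 26), moca_sd = 2,
      p_male = 0.5
    ),
    scores = list(
      vfc = list(intercept = 20, slope = 20),
      vfp = list(intercept = 28, slope = 40),
      vfs = list(intercept = 40, slope = 10),
      sd = 6
    ),
    seed = 20260101) {
  stopifnot(all(group_sizes >= 2), length(group_sizes) >= 1)
  if (abs(noise$ar) >= 1) stop("AR(1) coefficient must lie in (-1, 1)", call. = FALSE)
  sds <- c(noise$obs_sd, noise$drift_amp, noise$motion_sd, scores$sd,
           effects$subject_sd %||% 0)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  structure(
    list(group_sizes = group_sizes, effects = effects,
         base_within = base_within, base_between = base_between,
         noise = noise, task_amp = task_amp, covariates = covariates,
         scores = scores, seed = seed),
    class = "vf_cohort_config"
  )
}

# Resolve an effect-map entry: default targets are the other members of
# the seed region's cortex block.
resolve_effect <- function(effect, regions) {
  if (is.null(effect) || is.null(effect$seed_region)) return(NULL)
  if (!effect$seed_region %in% regions$name) {
    stop(sprintf("unknown seed region '%s'", effect$seed_region), call. = FALSE)
  }
  if (is.null(effect$targets)) {
    ctx <- regions$cortex[regions$name == effect$seed_region]
    effect$targets <- setdiff(regions$name[regions$cortex == ctx],
                              effect$seed_region)
  }
  effect
}

#' Group-level target correlation structure
#'
#' Block-structured baseline (within-cortex `base_within`, between-cortex
#' `base_between`) plus the group's additive offsets on the seed region's
#' edges, repaired to positive semi-definiteness by eigenvalue clipping
#' when necessary.
#'
#' @param group group label present in `config$group_sizes`.
#' @param regions region table ([make_region_table()]).
#' @param config a [cohort_config()].
#' @param extra_offset additional correlation-scale shift on the seed
#'   edges (per-subject jitter).
#' @return regions x regions correlation matrix.
#' @export
target_correlation <- function(group, regions, config, extra_offset = 0) {
  if (!group %in% names(config$group_sizes)) {
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  }
  n <- nrow(regions)
  same <- outer(regions$cortex, regions$cortex, "==")
  C <- ifelse(same, config$base_within, config$base_between)
  diag(C) <- 1
  dimnames(C) <- list(regions$name, regions$name)
  eff <- resolve_effect(config$effects[[group]], regions)
  if (!is.null(eff)) {
    shift <- (eff$offset %||% 0) + extra_offset
    if (shift != 0) {
      i <- match(eff$seed_region, regions$name)
      j <- match(eff$targets, regions$name)
      C[i, j] <- pmin(pmax(C[i, j] + shift, -0.99), 0.99)
      C[j, i] <- C[i, j]
    }
  }
  nearest_psd_correlation(C, warn = TRUE)
}

# Per-region task amplitude vector from the per-cortex amplitudes.
region_task_amplitudes <- function(regions, task_amp) {
  amp <- rep(task_amp$other %||% 0, nrow(regions))
  amp[regions$cortex == "left-frontal"] <- task_amp$left_frontal %||% 0
  amp[regions$cortex == "right-frontal"] <- task_amp$right_frontal %||% 0
  amp[regions$cortex == "left-temporal"] <- task_amp$left_temporal %||% 0
  amp
}

#' Simulate one subject's ROI time series and confound channels
#'
#' Latent multivariate Gaussian innovations with the group's target
#' correlation structure are AR(1)-smoothed in time, then a per-region
#' task response (HRF-convolved boxcar), low-frequency drift,
#' nuisance-channel leakage, white observation noise, and global spikes
#' at outlier frames are added. Six motion parameters evolve as a random
#' walk with jumps at the outlier frames.
#'
#' @param group group label.
#' @param design a [make_design()].
#' @param regions region table.
#' @param config a [cohort_config()].
#' @param seed integer seed for this subject.
#' @return A list: `series` (`vf_series`: regions x timepoints matrix
#'   with attributes `tr_s`, region dimnames), `motion` (timepoints x 6),
#'   `nuisance` (timepoints x n), `outlier_frames` (logical), and
#'   `target_seed_conn` (the subject's generative mean seed-edge
#'   correlation, used by the score model).
#' @export
simulate_subject <- function(group, design, regions, config, seed) {
  stopifnot(inherits(design, "vf_design"), inherits(config, "vf_cohort_config"))
  n <- nrow(regions)
  Tn <- design$n_timepoints
  nz <- config$noise
  with_local_seed(seed, {
    jitter <- stats::rnorm(1, 0, config$effects$subject_sd %||% 0)
    C <- target_correlation(group, regions, config, extra_offset = jitter)
    R <- chol(C)
    E <- matrix(stats::rnorm(Tn * n), Tn, n) %*% R
    # AR(1) smoothing with stationary unit variance: preserves the
    # cross-region correlation structure of the innovations.
    if (nz$ar != 0) {
      X <- stats::filter(E, nz$ar, method = "recursive")
      X <- matrix(as.numeric(X), Tn, n) * sqrt(1 - nz$ar^2)
    } else {
      X <- E
    }
    tt <- (seq_len(Tn) - 1) * design$tr_s
    task <- task_regressor(design)[, "task"]
    amp <- region_task_amplitudes(regions, config$task_amp)
    X <- X + outer(task, amp)
    if (nz$drift_amp > 0) {
      phase <- stats::runif(n, 0, 2 * pi)
      drift <- nz$drift_amp *
        cos(outer(2 * pi * tt / nz$drift_period_s, rep(1, n)) +
              matrix(phase, Tn, n, byrow = TRUE))
      X <- X + drift
    }
    n_nuis <- nz$n_nuisance %||% 0
    nuis <- matrix(0, Tn, max(n_nuis, 1))[, seq_len(n_nuis), drop = FALSE]
    if (n_nuis > 0) {
      nuis <- vapply(seq_len(n_nuis), function(k) {
        as.numeric(stats::filter(stats::rnorm(Tn), 0.3, method = "recursive"))
      }, numeric(Tn))
      colnames(nuis) <- paste0("nuisance", seq_len(n_nuis))
      X <- X + (nz$nuisance_load %||% 0) * rowSums(nuis) %o% rep(1, n) / n_nuis
    }
    if (nz$obs_sd > 0) X <- X + matrix(stats::rnorm(Tn * n, 0, nz$obs_sd), Tn, n)
    out_frames <- stats::runif(Tn) < (nz$outlier_prob %||% 0)
    if (any(out_frames)) X[out_frames, ] <- X[out_frames, ] + nz$spike_amp
    motion <- apply(matrix(stats::rnorm(Tn * 6, 0, nz$motion_sd), Tn, 6), 2, cumsum)
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    if (any(out_frames)) motion[out_frames, 1] <- motion[out_frames, 1] + 1.5
    series <- t(X)
    dimnames(series) <- list(regions$name, NULL)
    eff <- resolve_effect(config$effects[[group]], regions)
    seed_conn <- if (is.null(eff)) NA_real_ else {
      mean(C[eff$seed_region, eff$targets])
    }
    list(
      series = new_vf_series(series, design$tr_s),
      motion = motion, nuisance = nuis, outlier_frames = out_frames,
      target_seed_conn = seed_conn
    )
  })
}

#' ROI time-series container
#'
#' A regions x timepoints numeric matrix carrying the sampling interval
#' as attribute `tr_s` and region names as row names.
#'
#' @param mat regions x timepoints matrix with region row names.
#' @param tr_s sampling interval, seconds (> 0).
#' @param prepped logical provenance flag: has the series been denoised
#'   and filtered?
#' @return A `vf_series` object.
#' @export
new_vf_series <- function(mat, tr_s, prepped = FALSE) {
  stopifnot(is.matrix(mat), is.numeric(mat), tr_s > 0)
  if (anyNA(mat)) stop("time series must not contain missing values", call. = FALSE)
  structure(mat, tr_s = tr_s, prepped = prepped, class = c("vf_series", "matrix", "array"))
}

#' @export
print.vf_series <- function(x, ...) {
  cat(sprintf("<vf_series> %d regions x %d timepoints, TR %g s%s\n",
              nrow(x), ncol(x), attr(x, "tr_s"),
              if (isTRUE(attr(x, "prepped"))) " (prepped)" else ""))
  invisible(x)
}

#' Simulate a full cohort
#'
#' One subject per configured slot; covariates and behavioural scores are
#' drawn per subject, with VFC/VFP/VFS linearly linked to the subject's
#' generative seed-region mean connectivity. Per-subject seeds are
#' derived deterministically from the master seed, so identical
#' (config, design, regions) reproduce identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param design a [make_design()].
#' @param regions a region table; default [make_region_table()].
#' @return An object of class `vf_cohort`: list with `subjects`
#'   (data.frame), `series` / `motion` / `nuisance` / `outlier_frames`
#'   (named lists keyed by subject id), `regions`, `design`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), design = make_design(),
                            regions = make_region_table()) {
  stopifnot(inherits(config, "vf_cohort_config"))
  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n_sub <- length(groups)
  ids <- sprintf("S%03d", seq_len(n_sub))
  cv <- config$covariates
  sc <- config$scores
  series <- motion <- nuisance <- outliers <- stats::setNames(vector("list", n_sub), ids)
  age <- edu <- moca <- vfc <- vfp <- vfs <- seed_conn <- numeric(n_sub)
  sex <- character(n_sub)
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    sub <- simulate_subject(g, design, regions, config,
                            seed = derive_seed(config$seed, i, salt = 1L))
    series[[i]] <- sub$series
    motion[[i]] <- sub$motion
    nuisance[[i]] <- sub$nuisance
    outliers[[i]] <- sub$outlier_frames
    seed_conn[i] <- sub$target_seed_conn
    with_local_seed(derive_seed(config$seed, i, salt = 2L), {
      age[i] <- round(max(18, min(65, stats::rnorm(1, cv$age_mean[[g]], cv$age_sd))))
      sex[i] <- if (stats::runif(1) < cv$p_male) "male" else "female"
      edu[i] <- round(max(6, min(22, stats::rnorm(1, cv$edu_mean, cv$edu_sd))))
      moca[i] <- round(max(10, min(30, stats::rnorm(1, cv$moca_mean[[g]], cv$moca_sd))))
      mk <- function(m) max(0, m$intercept + m$slope * sub$target_seed_conn +
                              stats::rnorm(1, 0, sc$sd))
      vfc[i] <- mk(sc$vfc)
      vfp[i] <- mk(sc$vfp)
      vfs[i] <- mk(sc$vfs)
    })
  }
  subjects <- data.frame(
    id = ids, group = groups, age = age, sex = sex,
    sex01 = as.integer(sex == "male"), education = edu, moca = moca,
    vfc = vfc, vfp = vfp, vfs = vfs, seed_conn = seed_conn,
    li = NA_real_, dominance = NA_character_, stringsAsFactors = FALSE
  )
  structure(
    list(subjects = subjects, series = series, motion = motion,
         nuisance = nuisance, outlier_frames = outliers,
         regions = regions, design = design, config = config),
    class = "vf_cohort"
  )
}

#' @export
print.vf_cohort <- function(x, ...) {
  cat(sprintf("<vf_cohort> %d subjects (%s), %d regions, %d timepoints\n",
              nrow(x$subjects),
              paste(sprintf("%s n=%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = ", "),
              nrow(x$regions), x$design$n_timepoints))
  invisible(x)
}
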