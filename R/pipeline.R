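# End-to-end pipeline driver: simulate (or load) -> denoise ->
# connectivity -> degree-centrality AUC -> community/affinity ->
# activation GLM + laterality -> covariate-adjusted group statistics ->
# subgroup classification. All stage parameters default to the study's
# stated settings; all randomness derives from one master seed.

#' Pipeline configuration
#'
#' Defaults reproduce the analysis settings: band-pass 0.009-0.10 Hz,
#' densities 0.05-0.40 in steps of 0.01, 100 community optimizations,
#' alpha = 0.05 with FDR, and 70/30 x 100 repeated-split classification.
#'
#' @param out_dir output directory for the result bundle.
#' @param simulate generate a synthetic cohort (`TRUE`) or read one from
#'   `cohort_dir`.
#' @param cohort_dir directory holding a cohort written by
#'   [write_cohort()] (used when `simulate = FALSE`).
#' @param seed master seed for every stochastic stage.
#' @param cohort a [cohort_config()] override; `NULL` uses defaults with
#'   the master seed.
#' @param low_hz,high_hz band-pass edges (Hz).
#' @param z_thresh,motion_thresh_mm outlier-detection thresholds.
#' @param density_from,density_to,density_by proportional-threshold
#'   density grid.
#' @param community_runs Louvain optimizations per subject.
#' @param gamma modularity resolution.
#' @param alpha FDR level.
#' @param li_threshold t threshold for laterality mass.
#' @param train_frac,repetitions,p_enter,hidden classification settings.
#' @param max_class_features cap on the number of significant features
#'   offered to the classifier (ranked by omnibus F), keeping the
#'   stepwise search tractable.
#' @param do_community,do_classify stage toggles.
#' @param write_cohort_files also write the simulated cohort's series /
#'   confound files into the bundle (off by default: the bundle stays
#'   small and determinism is checked on the reports).
#' @return An object of class `vf_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = TRUE,
                            cohort_dir = NULL,
                            seed = 20260101,
                            cohort = NULL,
                            low_hz = 0.009, high_hz = 0.10,
                            z_thresh = 5, motion_thresh_mm = 0.9,
                            density_from = 0.05, density_to = 0.40,
                            density_by = 0.01,
                            community_runs = 100, gamma = 1,
                            alpha = 0.05, li_threshold = 2,
                            train_frac = 0.7, repetitions = 100,
                            p_enter = 0.05, hidden = 4,
                            max_class_features = 20,
                            do_community = TRUE, do_classify = TRUE,
                            write_cohort_files = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "vf_pipeline_config")
}

log_line <- function(log, stage, ...) {
  kv <- c(...)
  c(log, sprintf("stage=%s %s", stage,
                 paste(names(kv), kv, sep = "=", collapse = " ")))
}

hash_file <- function(path) fnv1a_hash(paste(readLines(path), collapse = "\n"))

#' Run the full analysis pipeline
#'
#' Executes every stage on a (simulated or loaded) cohort and writes a
#' result bundle: `subjects.csv` (with laterality columns filled),
#' `edge_stats.csv` + `edge_pairwise.csv`, `dcauc.csv` +
#' `dcauc_stats.csv`, `affinity.csv` + `affinity_stats.csv`,
#' `behaviour.csv` (HC-standardized scores and partial correlations in
#' `behaviour_correlations.csv`), `classification.json`, and a
#' structured `pipeline.log` whose lines carry the configuration hash
#' and per-output content hashes (no wall-clock entries, so two runs
#' with the same seed produce byte-identical bundles).
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "vf_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- fnv1a_hash(paste(deparse(config[setdiff(names(config), "out_dir")]),
                               collapse = ""))
  log <- character(0)
  log <- log_line(log, "config", hash = cfg_hash, seed = config$seed)

  # ---- cohort ---------------------------------------------------------
  if (isTRUE(config$simulate)) {
    cc <- config$cohort %||% cohort_config(seed = config$seed)
    cohort <- simulate_cohort(cc)
    log <- log_line(log, "simulate", subjects = nrow(cohort$subjects),
                    regions = nrow(cohort$regions))
  } else {
    if (is.null(config$cohort_dir) || !file.exists(file.path(config$cohort_dir, "subjects.csv"))) {
      stop(sprintf("cohort input not found: %s",
                   file.path(config$cohort_dir %||% "<unset>", "subjects.csv")),
           call. = FALSE)
    }
    cohort <- read_cohort(config$cohort_dir)
    log <- log_line(log, "load", dir = config$cohort_dir,
                    subjects = nrow(cohort$subjects))
  }
  if (isTRUE(config$write_cohort_files)) {
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
  }
  regions <- cohort$regions
  subjects <- cohort$subjects
  ids <- subjects$id
  rois <- regions$name[regions$is_roi]

  # ---- denoising ------------------------------------------------------
  prepped <- lapply(ids, function(id) {
    prep_series(cohort$series[[id]], cohort$motion[[id]],
                nuisance = cohort$nuisance[[id]], design = cohort$design,
                low_hz = config$low_hz, high_hz = config$high_hz,
                z_thresh = config$z_thresh,
                motion_thresh_mm = config$motion_thresh_mm)
  })
  names(prepped) <- ids
  log <- log_line(log, "prep", band = sprintf("%g-%g", config$low_hz, config$high_hz))

  # ---- connectivity + edge features ----------------------------------
  matrices <- lapply(prepped, correlation_matrix)
  edge_feat <- extract_edge_features(matrices, rois)
  log <- log_line(log, "connectivity", edges = ncol(edge_feat) - 1L)

  # ---- degree-centrality AUC -----------------------------------------
  grid <- density_grid(config$density_from, config$density_to, config$density_by)
  dcauc_tab <- t(vapply(matrices, function(M) dc_auc(M, grid)$auc[rois],
                        numeric(length(rois))))
  colnames(dcauc_tab) <- paste0("dcauc_", rois)
  dcauc_df <- data.frame(subject_id = ids, dcauc_tab, check.names = FALSE,
                         stringsAsFactors = FALSE)
  log <- log_line(log, "graphmetrics", densities = length(grid))

  # ---- community / affinity ------------------------------------------
  affinity_df <- NULL
  if (isTRUE(config$do_community)) {
    subnet <- regions$name[regions$cortex %in% c("left-frontal", "left-temporal")]
    aff_rows <- lapply(seq_along(ids), function(i) {
      W <- nonnegative_weights(matrices[[i]][subnet, subnet])
      P <- consensus_coassignment(W, runs = config$community_runs,
                                  master_seed = derive_seed(config$seed, i, salt = 6L),
                                  gamma = config$gamma)
      at <- affinity_table(P, regions[regions$name %in% subnet, ], rois,
                           cortices = c("left-frontal", "left-temporal"))
      cbind(subject_id = ids[i], at, stringsAsFactors = FALSE)
    })
    affinity_df <- do.call(rbind, aff_rows)
    log <- log_line(log, "community", runs = config$community_runs,
                    nodes = length(subnet))
  }

  # ---- activation GLM + laterality -----------------------------------
  X <- design_matrix(cohort$design)
  li_rows <- lapply(ids, function(id) {
    glm_res <- fit_glm(cohort$series[[id]], X)
    tv <- stats::setNames(glm_res$t, glm_res$region)
    li <- laterality_index(tv, regions, "frontal", config$li_threshold)
    data.frame(id = id, li = li$li, dominance = li$dominance,
               stringsAsFactors = FALSE)
  })
  li_df <- do.call(rbind, li_rows)
  subjects$li <- li_df$li[match(subjects$id, li_df$id)]
  subjects$dominance <- li_df$dominance[match(subjects$id, li_df$id)]
  log <- log_line(log, "taskglm", threshold = config$li_threshold)

  # ---- group statistics ----------------------------------------------
  covars <- subjects[, c("age", "sex01", "education", "moca")]
  edge_stats <- group_compare(edge_feat[, -1], subjects$group, covars,
                              alpha = config$alpha)
  dc_stats <- group_compare(dcauc_df[, -1, drop = FALSE], subjects$group, covars,
                            alpha = config$alpha)
  aff_stats <- NULL
  aff_wide <- NULL
  if (!is.null(affinity_df)) {
    key <- paste0("aff_", affinity_df$roi, "_", affinity_df$cortex)
    aff_wide <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
    for (k in unique(key)) {
      sel <- key == k
      aff_wide[[k]] <- affinity_df$affinity[sel][match(ids, affinity_df$subject_id[sel])]
    }
    aff_stats <- group_compare(aff_wide[, -1, drop = FALSE], subjects$group,
                               covars, alpha = config$alpha)
  }
  log <- log_line(log, "stats", alpha = config$alpha,
                  edge_significant = sum(edge_stats$omnibus$reject))

  # ---- behaviour: HC standardization + partial correlations ----------
  hc_mask <- subjects$group == "HC"
  behaviour <- subjects[, c("id", "group", "vfc", "vfp", "vfs")]
  if (any(hc_mask)) {
    for (sc in c("vfc", "vfp", "vfs")) {
      behaviour[[paste0(sc, "_z")]] <- standardize_scores(subjects[[sc]], hc_mask)
    }
  }
  pc_rows <- lapply(unique(subjects$group), function(g) {
    gi <- subjects$group == g
    if (sum(gi) <= ncol(covars) + 3) return(NULL) # too few for adjustment
    do.call(rbind, lapply(c("vfp", "vfs"), function(other) {
      pc <- partial_correlation(subjects$vfc[gi], subjects[[other]][gi],
                                covars[gi, ])
      data.frame(group = g, pair = paste0("vfc~", other), r = pc$r, p = pc$p,
                 n = pc$n, stringsAsFactors = FALSE)
    }))
  })
  behav_cor <- do.call(rbind, pc_rows) %||%
    data.frame(group = character(0), pair = character(0), r = numeric(0),
               p = numeric(0), n = integer(0))
  behav_cor$q <- stats::p.adjust(behav_cor$p, method = "BH")

  # ---- classification -------------------------------------------------
  class_report <- NULL
  if (isTRUE(config$do_classify)) {
    pat <- subjects$group %in% c("TLE-HS", "TLE-NHS")
    if (sum(pat) >= 8 && length(unique(subjects$group[pat])) == 2) {
      sig_feats <- list()
      om <- edge_stats$omnibus
      sig_edges <- om$feature[om$reject]
      if (length(sig_edges)) {
        ord <- order(-om$F[match(sig_edges, om$feature)])
        sig_edges <- sig_edges[ord][seq_len(min(length(sig_edges),
                                                config$max_class_features))]
        sig_feats$edges <- edge_feat[pat, sig_edges, drop = FALSE]
      }
      if (any(dc_stats$omnibus$reject)) {
        sig_feats$dc <- dcauc_df[pat, dc_stats$omnibus$feature[dc_stats$omnibus$reject],
                                 drop = FALSE]
      }
      if (!is.null(aff_stats) && any(aff_stats$omnibus$reject)) {
        sig_feats$aff <- aff_wide[pat, aff_stats$omnibus$feature[aff_stats$omnibus$reject],
                                  drop = FALSE]
      }
      feat <- data.frame(vfc = behaviour$vfc_z[pat], vfp = behaviour$vfp_z[pat],
                         vfs = behaviour$vfs_z[pat], check.names = FALSE)
      if (length(sig_feats)) {
        feat <- cbind(feat, do.call(cbind, unname(sig_feats)))
      }
      labels <- factor(subjects$group[pat])
      sw_full <- forward_stepwise_logistic(feat, labels, p_enter = config$p_enter)
      insample <- if (length(sw_full$selected)) {
        net <- train_nn(feat[, sw_full$selected, drop = FALSE], labels,
                        hidden = config$hidden,
                        seed = derive_seed(config$seed, 1L, salt = 7L))
        roc_auc(predict(net, feat[, sw_full$selected, drop = FALSE]), labels)
      } else NA_real_
      split_eval <- evaluate_repeated_split(
        feat, labels, model = "stepwise_nn", train_frac = config$train_frac,
        repetitions = config$repetitions,
        master_seed = derive_seed(config$seed, 2L, salt = 7L),
        p_enter = config$p_enter, hidden = config$hidden
      )
      class_report <- list(
        n = sum(pat), candidate_features = colnames(feat),
        selected_full_sample = sw_full$selected,
        separation = sw_full$separation,
        auc_in_sample = insample,
        auc_split_mean = split_eval$mean_auc,
        auc_split_ci95 = split_eval$ci95,
        repetitions = split_eval$repetitions
      )
      log <- log_line(log, "classify",
                      selected = length(sw_full$selected),
                      mean_auc = sprintf("%.4f", split_eval$mean_auc))
    }
  }

  # ---- write bundle ---------------------------------------------------
  out <- function(name) file.path(config$out_dir, name)
  write_table_file(subjects, out("subjects.csv"), ",", kind = "subjects")
  write_table_file(edge_stats$omnibus, out("edge_stats.csv"), ",",
                   kind = "edge_stats")
  if (!is.null(edge_stats$pairwise)) {
    write_table_file(edge_stats$pairwise, out("edge_pairwise.csv"), ",",
                     kind = "edge_pairwise")
  }
  write_table_file(dcauc_df, out("dcauc.csv"), ",", kind = "dcauc")
  write_table_file(dc_stats$omnibus, out("dcauc_stats.csv"), ",",
                   kind = "dcauc_stats")
  if (!is.null(affinity_df)) {
    write_table_file(affinity_df, out("affinity.csv"), ",", kind = "affinity")
    write_table_file(aff_stats$omnibus, out("affinity_stats.csv"), ",",
                     kind = "affinity_stats")
  }
  write_table_file(behaviour, out("behaviour.csv"), ",", kind = "behaviour")
  write_table_file(behav_cor, out("behaviour_correlations.csv"), ",",
                   kind = "behaviour_correlations")
  if (!is.null(class_report)) {
    jsonlite::write_json(class_report, out("classification.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  for (f in list.files(config$out_dir, pattern = "\\.(csv|json)$")) {
    log <- log_line(log, "output", file = f, hash = hash_file(out(f)))
  }
  writeLines(log, out("pipeline.log"))

  invisible(list(
    cohort = cohort, subjects = subjects, edge_features = edge_feat,
    edge_stats = edge_stats, dcauc = dcauc_df, dc_stats = dc_stats,
    affinity = affinity_df, affinity_stats = aff_stats,
    behaviour = behaviour, behaviour_correlations = behav_cor,
    classification = class_report, log = log
  ))
}
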