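# Independent oracles and small fixtures shared across tests. Oracles
# are deliberately naive (double sums, brute-force enumeration) and do
# not call the implementation paths they check.

# Direct double-sum modularity oracle.
modularity_oracle <- function(W, membership, gamma = 1) {
  n <- nrow(W)
  m2 <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + W[i, j] - gamma * k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

# All set partitions of n elements as membership vectors (restricted
# growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum modularity over all partitions.
max_modularity_oracle <- function(W, gamma = 1) {
  parts <- all_partitions(nrow(W))
  max(vapply(parts, function(p) modularity_oracle(W, p, gamma), numeric(1)))
}

# Trapezoid quadrature oracle.
trapz_oracle <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# Symmetric random weighted matrix with positive weights, zero diagonal.
random_weight_matrix <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2)
  W + t(W)
}

# Two disconnected equal-weight 4-cliques (weight 1 edges).
two_cliques <- function() {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  dimnames(W) <- list(paste0("n", 1:8), paste0("n", 1:8))
  W
}

# Reduced region table: `blocks` named cortex blocks of `per` regions
# each; the first region of the first block is flagged as ROI unless a
# roi vector is given.
mini_regions <- function(per = 5,
                         blocks = c("left-frontal", "left-temporal"),
                         rois = NULL) {
  tab <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    data.frame(
      name = paste0(gsub("[^a-zA-Z]", "", blocks[b]), seq_len(per)),
      hemisphere = if (grepl("^right", blocks[b])) "right" else "left",
      cortex = blocks[b], stringsAsFactors = FALSE
    )
  }))
  if (is.null(rois)) rois <- tab$name[1]
  tab$is_roi <- tab$name %in% rois
  tab
}

# A small quiet cohort configuration for fast end-to-end tests.
mini_config <- function(group_sizes = c("HC" = 3, "TLE-HS" = 3, "TLE-NHS" = 3),
                        seed = 7, seed_region = "leftfrontal1",
                        offsets = c("HC" = 0, "TLE-HS" = -0.25, "TLE-NHS" = 0.15),
                        subject_sd = 0.05, ...) {
  cohort_config(
    group_sizes = group_sizes,
    effects = list(
      "HC" = list(seed_region = seed_region, targets = NULL,
                  offset = offsets[["HC"]]),
      "TLE-HS" = list(seed_region = seed_region, targets = NULL,
                      offset = offsets[["TLE-HS"]]),
      "TLE-NHS" = list(seed_region = seed_region, targets = NULL,
                       offset = offsets[["TLE-NHS"]]),
      subject_sd = subject_sd
    ),
    seed = seed, ...
  )
}

# Noise-free settings: latent structure only.
quiet_noise <- function() {
  list(ar = 0, obs_sd = 0, drift_amp = 0, drift_period_s = 128,
       nuisance_load = 0, n_nuisance = 0, motion_sd = 0,
       outlier_prob = 0, spike_amp = 0)
}

no_task <- function() {
  list(left_frontal = 0, right_frontal = 0, left_temporal = 0, other = 0)
}
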