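# Weighted modularity, a seeded Louvain-style optimizer, repeated-run
# consensus co-assignment, and region-to-cortex affinity.

#' Zero out negative weights
#'
#' Community detection operates on non-negative weights; negative
#' correlations are set to 0 before optimization.
#'
#' @param W symmetric weighted matrix.
#' @return `W` with negative entries replaced by 0.
#' @export
nonnegative_weights <- function(W) {
  W[W < 0] <- 0
  W
}

check_community_matrix <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be square", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric", call. = FALSE)
  if (any(W < 0)) {
    stop("W has negative weights; zero them first (nonnegative_weights())", call. = FALSE)
  }
  if (sum(W) <= 0) stop("W has zero total weight", call. = FALSE)
  invisible(TRUE)
}

#' Newman-Girvan weighted modularity
#'
#' `Q = (1/2m) * sum_ij (W_ij - gamma * k_i k_j / 2m) * delta(c_i, c_j)`
#' with `m` half the total edge weight and `gamma` the resolution
#' parameter. The sum runs over all ordered pairs including `i = j`, so
#' the single-community partition always has `Q = 0` at `gamma = 1`.
#'
#' @param W symmetric non-negative weighted matrix (zero diagonal at the
#'   region level; aggregated networks may carry self-loops).
#' @param membership integer community label per node.
#' @param gamma resolution parameter (default 1).
#' @return Scalar modularity Q.
#' @export
modularity_q <- function(W, membership, gamma = 1) {
  check_community_matrix(W)
  stopifnot(length(membership) == nrow(W))
  m2 <- sum(W)
  k <- rowSums(W)
  comm <- as.integer(factor(membership))
  S <- outer(comm, comm, "==")
  sum((W - gamma * tcrossprod(k) / m2) * S) / m2
}

# One Louvain level: greedy local moves on W from an initial labelling
# until no gain. Node visit order is reshuffled each pass from the
# active RNG stream. Ties in move gain keep the current community.
louvain_local_moves <- function(W, gamma, comm = seq_len(nrow(W))) {
  n <- nrow(W)
  m2 <- sum(W)
  k <- rowSums(W)
  # per-community total strength, indexed by label (labels <= n always)
  sigma_tot <- numeric(n)
  agg <- rowsum(k, comm)
  sigma_tot[as.integer(rownames(agg))] <- agg[, 1]
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      # strength from i into each community (self-loop excluded: it is
      # community-invariant)
      w_row <- W[i, ]
      w_row[i] <- 0
      links <- rowsum(w_row, comm, reorder = FALSE)
      comms <- as.integer(rownames(links))
      # remove i from its community
      sigma_tot[ci] <- sigma_tot[ci] - k[i]
      gain <- links[, 1] - gamma * k[i] * sigma_tot[comms] / m2
      cur <- match(ci, comms)
      base <- if (is.na(cur)) 0 else gain[cur] # gain of rejoining own
      best <- which.max(gain)
      # strict improvement required; ties keep the current community
      target <- if (gain[best] > base + 1e-12) comms[best] else ci
      comm[i] <- target
      sigma_tot[target] <- sigma_tot[target] + k[i]
      if (target != ci) improved <- TRUE
    }
    if (!improved) break
  }
  as.integer(factor(comm))
}

# One full two-phase optimization from an initial flat labelling.
louvain_once <- function(W, gamma, init) {
  n <- nrow(W)
  membership <- louvain_local_moves(W, gamma, init)
  q_prev <- modularity_q(W, membership, gamma)
  repeat {
    # aggregate: super-node network with self-loops
    S <- outer(membership, seq_len(max(membership)), "==") + 0
    Wl <- t(S) %*% W %*% S
    if (nrow(Wl) == n) break
    local <- louvain_local_moves(Wl, gamma)
    membership2 <- local[membership]
    q_new <- modularity_q(W, membership2, gamma)
    if (q_new <= q_prev + 1e-10) break
    membership <- membership2
    q_prev <- q_new
  }
  list(membership = as.integer(factor(membership)), Q = q_prev)
}

#' Louvain-style modularity optimization (seeded)
#'
#' Greedy two-phase algorithm: local node moves in randomized order
#' until no modularity gain, then aggregation of communities into
#' super-nodes; phases repeat until a full level improves Q by less than
#' `1e-10`. To escape the local optima that pure greedy descent from
#' singletons is prone to on small dense graphs, the optimization is
#' repeated `restarts` times — the first pass from the canonical
#' all-singletons start, later passes from seeded random initial
#' partitions — and the best-Q partition is returned. Deterministic
#' given `seed`; Q never decreases across levels within a pass.
#'
#' @param W symmetric non-negative weighted matrix, zero diagonal.
#' @param gamma resolution parameter.
#' @param seed integer seed controlling node-visit shuffles and restart
#'   initializations.
#' @param restarts number of independent starts (default 5).
#' @return A list of class `vf_partition`: `membership` (integer labels,
#'   contiguous from 1), `Q` (modularity of the returned partition), and
#'   `n_communities`.
#' @export
louvain <- function(W, gamma = 1, seed = 1L, restarts = 5) {
  check_community_matrix(W)
  n <- nrow(W)
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- with_local_seed(derive_seed(seed, r, salt = 8L), {
      init <- if (r == 1) seq_len(n) else {
        sample.int(max(2L, n %/% 2L), n, replace = TRUE)
      }
      louvain_once(W, gamma, init)
    })
    if (is.null(best) || res$Q > best$Q + 1e-12) best <- res
  }
  structure(
    list(membership = stats::setNames(best$membership, rownames(W)),
         Q = modularity_q(W, best$membership, gamma),
         n_communities = max(best$membership)),
    class = "vf_partition"
  )
}

#' @export
print.vf_partition <- function(x, ...) {
  cat(sprintf("<vf_partition> %d communities, Q = %.4f\n", x$n_communities, x$Q))
  invisible(x)
}

#' Consensus co-assignment matrix over repeated Louvain runs
#'
#' `P_ij` is the fraction of runs in which nodes `i` and `j` fall in the
#' same community; per-run seeds derive deterministically from
#' `master_seed`. The diagonal is 1 and every entry is a multiple of
#' `1/runs`.
#'
#' @param W symmetric non-negative weighted matrix.
#' @param runs number of optimizations (default 100).
#' @param master_seed master seed for the run seeds.
#' @param gamma resolution parameter.
#' @return A `vf_coassignment` matrix (nodes x nodes) with attribute
#'   `runs`.
#' @export
consensus_coassignment <- function(W, runs = 100, master_seed = 1L, gamma = 1) {
  stopifnot(runs >= 1)
  n <- nrow(W)
  P <- matrix(0, n, n, dimnames = dimnames(W))
  for (r in seq_len(runs)) {
    part <- louvain(W, gamma = gamma, seed = derive_seed(master_seed, r, salt = 3L))
    P <- P + outer(part$membership, part$membership, "==")
  }
  P <- P / runs
  diag(P) <- 1
  structure(P, runs = runs, class = c("vf_coassignment", "matrix", "array"))
}

#' Affinity of a region to a cortex
#'
#' The mean co-assignment probability between region `i` and the members
#' of cortex X (excluding `i` itself when it belongs to X):
#' `A_iX = (1/n_Xi) * sum_{j in X, j != i} P_ij`.
#'
#' @param P a co-assignment matrix with region dimnames.
#' @param region region name (or index).
#' @param cortex_members names (or indices) of the cortex's regions.
#' @return A list: `region`, `value` (in \[0, 1\]), `n` (number of
#'   contributing regions).
#' @export
affinity <- function(P, region, cortex_members) {
  nm <- rownames(P)
  idx <- function(x) if (is.character(x)) match(x, nm) else as.integer(x)
  i <- idx(region)
  js <- idx(cortex_members)
  if (anyNA(c(i, js))) stop("unknown region label(s)", call. = FALSE)
  js <- setdiff(js, i)
  if (!length(js)) {
    stop("cortex contains no regions other than the target region (n_Xi = 0)",
         call. = FALSE)
  }
  list(region = if (is.character(region)) region else nm[i] %||% i,
       value = mean(P[i, js]), n = length(js))
}

#' Affinity table for a set of ROIs against a set of cortices
#'
#' @param P co-assignment matrix with region dimnames.
#' @param regions region table (with `name`, `cortex`) restricted to the
#'   nodes of `P`.
#' @param rois ROI names to score.
#' @param cortices cortex labels to score against (default: all cortex
#'   labels present).
#' @return data.frame with columns `roi`, `cortex`, `affinity`, `n`.
#' @export
affinity_table <- function(P, regions, rois, cortices = unique(regions$cortex)) {
  rows <- list()
  for (roi in rois) {
    for (ctx in cortices) {
      members <- regions$name[regions$cortex == ctx]
      members <- intersect(members, rownames(P))
      members_excl <- setdiff(members, roi)
      if (!length(members_excl)) next
      a <- affinity(P, roi, members)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, cortex = ctx, affinity = a$value, n = a$n,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
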