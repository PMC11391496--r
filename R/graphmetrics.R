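# Proportional thresholding over a density grid, degree centrality and
# its area under the curve.

#' Density grid for proportional thresholding
#'
#' @param from,to,by grid limits and step as edge-density fractions.
#'   Defaults 0.05 to 0.40 in steps of 0.01 (36 densities).
#' @return Strictly increasing numeric vector of densities in (0, 1].
#' @export
density_grid <- function(from = 0.05, to = 0.40, by = 0.01) {
  g <- seq(from, to, by = by)
  if (any(g <= 0 | g > 1) || any(diff(g) <= 0)) {
    stop("densities must be strictly increasing and lie in (0, 1]", call. = FALSE)
  }
  g
}

#' Binarize a weighted matrix at a fixed connection density
#'
#' Keeps the `k = round(d * M)` highest-weight edges of the
#' `M = n(n-1)/2` upper-triangle entries (signed value, not absolute,
#' unless `abs = TRUE`); rounding is half-up. Ties are broken by
#' lexicographic (i, j) order after a stable descending sort, so the
#' result is fully deterministic.
#'
#' @param W symmetric weighted matrix (`vf_connectivity` or plain).
#' @param d target density in (0, 1].
#' @param abs rank edges by absolute weight instead of signed weight.
#' @return Symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
threshold_by_density <- function(W, d, abs = FALSE) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d > 1) {
    stop("density must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE] # lexicographic (i, j)
  w <- W[ut]
  if (abs) w <- base::abs(w)
  M <- nrow(ut)
  k <- floor(d * M + 0.5) # half-up rounding
  A <- matrix(0L, n, n, dimnames = dimnames(W))
  if (k > 0) {
    keep <- order(-w, ut[, 1], ut[, 2])[seq_len(k)] # ties: lexicographic (i, j)
    A[ut[keep, , drop = FALSE]] <- 1L
    A[ut[keep, c(2, 1), drop = FALSE]] <- 1L
  }
  A
}

#' Degree centrality of a binary graph
#'
#' The number of suprathreshold connections linked to each node: row
#' sums of the adjacency matrix.
#'
#' @param A symmetric 0/1 adjacency matrix, zero diagonal.
#' @return Named integer vector of node degrees.
#' @export
degree_centrality <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  rowSums(A != 0)
}

#' Degree curves and their area under the curve across densities
#'
#' Thresholds the weighted matrix at every density of the grid, computes
#' degree centrality, and integrates each node's degree-versus-density
#' curve by the trapezoid rule (`method = "trapezoid"`) or a plain step
#' sum `sum(degree) * by` (`method = "sum"`, for sensitivity checks).
#'
#' @param W symmetric weighted matrix.
#' @param grid density grid from [density_grid()]; length >= 2.
#' @param method `"trapezoid"` (default) or `"sum"`.
#' @param abs passed to [threshold_by_density()].
#' @return A list: `degree` (nodes x densities matrix) and `auc` (named
#'   per-node vector).
#' @export
dc_auc <- function(W, grid = density_grid(), method = c("trapezoid", "sum"),
                   abs = FALSE) {
  method <- match.arg(method)
  if (length(grid) < 2) stop("density grid must have at least 2 points", call. = FALSE)
  n <- nrow(W)
  deg <- vapply(grid, function(d) degree_centrality(threshold_by_density(W, d, abs = abs)),
                numeric(n))
  rownames(deg) <- rownames(W)
  colnames(deg) <- sprintf("d%.2f", grid)
  auc <- if (method == "trapezoid") {
    apply(deg, 1, function(y) pracma::trapz(grid, y))
  } else {
    rowSums(deg) * mean(diff(grid))
  }
  list(degree = deg, auc = auc)
}
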