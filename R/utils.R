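# Internal helpers: seeded RNG scoping, substream derivation, PSD repair,
# and a small string hash used for provenance headers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that no exported function perturbs
#' the caller's random-number stream. All stochastic operations in the
#' package route their randomness through this helper.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible substream seed
#'
#' Mixes a master seed with an index (and optional salt) through a
#' multiplicative congruential step modulo the Mersenne prime 2^31 - 1,
#' yielding independent, platform-stable substream seeds that always fit
#' in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @param salt optional extra integer to separate seed families.
#' @return A single integer in \[1, 2^31 - 2\].
#' @keywords internal
derive_seed <- function(master, index, salt = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.numeric(master)) %% m)
  # two Lehmer steps keyed by index and salt; doubles stay below 2^53
  x <- (x * 48271 + as.numeric(index) * 16807 + as.numeric(salt)) %% m
  x <- (x * 48271 + 1) %% m
  as.integer(x %% (m - 2) + 1)
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Clips eigenvalues below `eps`, reconstructs, and rescales to unit
#' diagonal. Used after additive edge offsets push a target correlation
#' structure outside the PSD cone.
#'
#' @param C symmetric matrix.
#' @param eps eigenvalue floor (default `1e-6`).
#' @param warn emit a warning when a repair was needed.
#' @return A positive semi-definite correlation matrix.
#' @keywords internal
nearest_psd_correlation <- function(C, eps = 1e-6, warn = TRUE) {
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) >= eps) {
    return(C)
  }
  if (warn) {
    warning(sprintf(
      "target correlation matrix not positive semi-definite (min eigenvalue %.3g); repaired by eigenvalue clipping at %g",
      min(ev$values), eps
    ), call. = FALSE)
  }
  vals <- pmax(ev$values, eps)
  R <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  dimnames(R) <- dimnames(C)
  R
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used only to stamp provenance headers; not cryptographic.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    hs <- if (h >= 2^31) h - 2^32 else h      # to signed 32-bit for bitwXor
    hx <- bitwXor(as.integer(hs), as.integer(b))
    h <- if (hx < 0) hx + 2^32 else hx
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    lo <- h %% 2^16
    hi <- (h - lo) / 2^16
    h <- (lo * 16777619 + (hi * 16777619 %% 2^16) * 2^16) %% 2^32
  }
  sprintf("%04x%04x", as.integer((h - h %% 2^16) / 2^16), as.integer(h %% 2^16))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memo store for deterministic, pure intermediates (task regressors)
.vf_cache <- new.env(parent = emptyenv())
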