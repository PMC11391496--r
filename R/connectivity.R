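# Per-subject weighted connectivity matrices and the ROI x region edge
# feature table compared across groups.

#' Pearson functional-connectivity matrix
#'
#' Pairwise Pearson correlation between the denoised time series of all
#' region pairs; the diagonal is set to 0 by convention. Constant
#' regions have undefined correlations: their row/column is set to 0
#' with a warning.
#'
#' @param series a `vf_series` with `prepped = TRUE` (set by
#'   [prep_series()]); raw series are rejected unless
#'   `allow_raw = TRUE`.
#' @param allow_raw bypass the provenance check (for tests on
#'   constructed signals).
#' @return A `vf_connectivity` object: symmetric regions x regions
#'   matrix in \[-1, 1\], zero diagonal, region dimnames.
#' @export
correlation_matrix <- function(series, allow_raw = FALSE) {
  if (!isTRUE(attr(series, "prepped")) && !allow_raw) {
    stop("series has not been denoised (prepped = FALSE); run prep_series() first or set allow_raw = TRUE",
         call. = FALSE)
  }
  if (ncol(series) < 3) stop("need at least 3 timepoints", call. = FALSE)
  X <- t(unclass(series))
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning(sprintf("%d constant region(s) (%s): correlations set to 0",
                    sum(const),
                    paste(rownames(series)[const], collapse = ", ")),
            call. = FALSE)
  }
  C <- matrix(0, nrow(series), nrow(series),
              dimnames = list(rownames(series), rownames(series)))
  ok <- which(!const)
  C[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
  C <- pmin(pmax((C + t(C)) / 2, -1), 1)
  diag(C) <- 0
  structure(C, class = c("vf_connectivity", "matrix", "array"))
}

#' Fisher's variance-stabilizing z-transform
#'
#' `z = atanh(r)`. Correlations at or beyond +/-1 are clipped to
#' +/-(1 - 1e-7) with a warning so downstream linear models never see
#' infinities.
#'
#' @param r correlation value(s).
#' @return Fisher z value(s); strictly increasing in `r`.
#' @examples
#' fisher_z(0.5) # 0.5493
#' @export
fisher_z <- function(r) {
  out_of_range <- abs(r) >= 1
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sprintf("%d correlation(s) with |r| >= 1 clipped to +/-(1 - 1e-7)",
                    sum(out_of_range, na.rm = TRUE)), call. = FALSE)
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' Edge-feature table: Fisher-z ROI connectivity across subjects
#'
#' One column per (ROI, other-region) pair, ROI first, with ROI-ROI
#' pairs appearing once (canonical ordering by region index); one row
#' per subject. With 6 ROIs among 132 regions this yields
#' 6 x 131 - choose(6, 2) = 771 columns.
#'
#' @param matrices named list of `vf_connectivity` matrices (one per
#'   subject, shared region labels).
#' @param rois character vector of ROI region names.
#' @return A data.frame with key column `subject_id` and one numeric
#'   Fisher-z column per edge, named `<ROI>__<region>`.
#' @export
extract_edge_features <- function(matrices, rois) {
  stopifnot(length(matrices) >= 1)
  labels <- rownames(matrices[[1]])
  if (is.null(labels)) stop("connectivity matrices must carry region names", call. = FALSE)
  bad <- setdiff(rois, labels)
  if (length(bad)) {
    stop(sprintf("unknown ROI label(s): %s. Valid labels are the %d region names of the connectivity matrices.",
                 paste(bad, collapse = ", "), length(labels)), call. = FALSE)
  }
  roi_idx <- match(rois, labels)
  pairs <- do.call(rbind, lapply(seq_along(rois), function(a) {
    i <- roi_idx[a]
    js <- setdiff(seq_along(labels), i)
    # drop ROI-ROI duplicates: keep only pairs where the partner is a
    # later-indexed ROI or a non-ROI region
    js <- js[!(js %in% roi_idx & js < i)]
    cbind(i = rep(i, length(js)), j = js)
  }))
  feat <- t(vapply(matrices, function(M) {
    if (!identical(rownames(M), labels)) {
      stop("all subjects must share identical region labels", call. = FALSE)
    }
    fisher_z(M[pairs])
  }, numeric(nrow(pairs))))
  colnames(feat) <- paste0(labels[pairs[, 1]], "__", labels[pairs[, 2]])
  out <- data.frame(subject_id = names(matrices) %||% as.character(seq_along(matrices)),
                    feat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
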