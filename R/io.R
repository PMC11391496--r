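# Plain-text I/O: TSV time series / confounds / matrices, CSV subject
# and region tables. Every writer stamps a '#'-prefixed provenance
# header; numeric values are written with 17 significant digits so a
# write-then-read round trip reproduces them to full double precision.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

provenance_header <- function(kind, extra = character(0)) {
  c(sprintf("# vfnet %s", kind), paste0("# ", extra))
}

read_text_table <- function(path, sep) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  body_start <- which(!is_comment)[1]
  if (is.na(body_start)) {
    stop(sprintf("%s: no table content found (line %d)", path, length(lines) + 1L),
         call. = FALSE)
  }
  header <- strsplit(lines[body_start], sep, fixed = TRUE)[[1]]
  if (!length(header) || any(header == "")) {
    stop(sprintf("%s: malformed header at line %d", path, body_start), call. = FALSE)
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "comments") <- lines[is_comment & seq_along(lines) < body_start]
  df
}

#' Write / read an ROI time series as TSV
#'
#' Rows are timepoints, columns are region names; `tr_s` and the
#' `prepped` provenance flag are stored in the header comments.
#'
#' @param series a `vf_series`.
#' @param path file path.
#' @return `read_series_tsv` returns a `vf_series`.
#' @export
write_series_tsv <- function(series, path) {
  hdr <- provenance_header("series", c(
    sprintf("tr_s=%.17g", attr(series, "tr_s")),
    sprintf("prepped=%s", isTRUE(attr(series, "prepped")))
  ))
  M <- t(unclass(series))
  body <- c(paste(rownames(series), collapse = "\t"),
            apply(M, 1, function(r) paste(fmt_num(r), collapse = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  tr <- sub("^# tr_s=", "", grep("^# tr_s=", meta, value = TRUE))
  prepped <- sub("^# prepped=", "", grep("^# prepped=", meta, value = TRUE))
  if (!length(tr)) {
    stop(sprintf("%s: malformed header: missing '# tr_s=' (line %d)", path,
                 min(which(!startsWith(lines, "#")), length(lines))), call. = FALSE)
  }
  df <- read_text_table(path, "\t")
  series <- t(as.matrix(df))
  new_vf_series(series, as.numeric(tr), prepped = identical(prepped, "TRUE"))
}

#' Write / read a symmetric labelled matrix as TSV
#'
#' Region labels form the header row and the first column.
#'
#' @param M matrix with identical row/column names.
#' @param path file path.
#' @param kind provenance tag written in the header.
#' @export
write_matrix_tsv <- function(M, path, kind = "matrix") {
  hdr <- provenance_header(kind)
  body <- c(paste(c("region", colnames(M)), collapse = "\t"),
            vapply(seq_len(nrow(M)), function(i) {
              paste(c(rownames(M)[i], fmt_num(M[i, ])), collapse = "\t")
            }, character(1)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_text_table(path, "\t")
  if (colnames(df)[1] != "region") {
    stop(sprintf("%s: malformed header: first column must be 'region' (line %d)",
                 path, length(attr(df, "comments")) + 1L), call. = FALSE)
  }
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$region
  M
}

#' Write / read a generic numeric table (confounds, features) as TSV/CSV
#'
#' @param df data.frame.
#' @param path file path.
#' @param sep field separator (`"\t"` or `","` by file use).
#' @param kind provenance tag.
#' @param required for the reader: column names that must be present;
#'   a missing column is an error naming it.
#' @export
write_table_file <- function(df, path, sep = "\t", kind = "table") {
  hdr <- provenance_header(kind)
  cols <- vapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1)
  body <- c(paste(colnames(df), collapse = sep),
            apply(cols, 1, paste, collapse = sep))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path, sep = "\t", required = NULL) {
  df <- read_text_table(path, sep)
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

subject_columns <- c("id", "group", "age", "sex", "sex01", "education",
                     "moca", "vfc", "vfp", "vfs")

#' Write a simulated cohort to a directory
#'
#' Layout: `subjects.csv`, `regions.csv`, `design.json`, and per-subject
#' `series/<id>.tsv` plus `confounds/<id>.tsv` (six motion columns, the
#' nuisance channels, and an `outlier` indicator column).
#'
#' @param cohort a `vf_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. `read_cohort` returns a `vf_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "confounds"), recursive = TRUE, showWarnings = FALSE)
  write_table_file(cohort$subjects, file.path(dir, "subjects.csv"), ",",
                   kind = "subjects")
  write_table_file(cohort$regions, file.path(dir, "regions.csv"), ",",
                   kind = "regions")
  jsonlite::write_json(
    cohort$design[c("n_blocks", "rest_s", "task_s", "tr_s")],
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA
  )
  for (id in cohort$subjects$id) {
    write_series_tsv(cohort$series[[id]], file.path(dir, "series", paste0(id, ".tsv")))
    conf <- data.frame(cohort$motion[[id]], cohort$nuisance[[id]],
                       outlier = as.integer(cohort$outlier_frames[[id]]),
                       check.names = FALSE)
    write_table_file(conf, file.path(dir, "confounds", paste0(id, ".tsv")), "\t",
                     kind = "confounds")
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- read_table_file(file.path(dir, "subjects.csv"), ",",
                              required = subject_columns)
  regions <- read_table_file(file.path(dir, "regions.csv"), ",",
                             required = c("name", "hemisphere", "cortex", "is_roi"))
  regions$is_roi <- as.logical(regions$is_roi)
  dj <- jsonlite::read_json(file.path(dir, "design.json"), simplifyVector = TRUE)
  design <- make_design(dj$n_blocks, dj$rest_s, dj$task_s, dj$tr_s)
  ids <- subjects$id
  series <- motion <- nuisance <- outliers <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    s <- read_series_tsv(file.path(dir, "series", paste0(id, ".tsv")))
    if (nrow(s) != nrow(regions)) {
      stop(sprintf("series for %s has %d regions but the region table has %d",
                   id, nrow(s), nrow(regions)), call. = FALSE)
    }
    series[[id]] <- s
    conf <- read_table_file(file.path(dir, "confounds", paste0(id, ".tsv")), "\t",
                            required = c("tx", "ty", "tz", "rx", "ry", "rz", "outlier"))
    motion[[id]] <- as.matrix(conf[, c("tx", "ty", "tz", "rx", "ry", "rz")])
    nuis_cols <- grep("^nuisance", colnames(conf), value = TRUE)
    nuisance[[id]] <- as.matrix(conf[, nuis_cols, drop = FALSE])
    outliers[[id]] <- conf$outlier == 1
  }
  structure(
    list(subjects = subjects, series = series, motion = motion,
         nuisance = nuisance, outlier_frames = outliers,
         regions = regions, design = design, config = NULL),
    class = "vf_cohort"
  )
}
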