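# YAML configuration file support for the cohort generator.

#' Read a cohort configuration from a YAML file
#'
#' The file holds flat keys and nested sections whose names match the
#' arguments of [cohort_config()] (`group_sizes`, `effects`,
#' `base_within`, `base_between`, `noise`, `task_amp`, `covariates`,
#' `scores`, `seed`); omitted keys keep their defaults and unknown keys
#' are rejected. See
#' `system.file("extdata/cohort-config-example.yaml", package = "vfnet")`
#' for a fully commented example.
#'
#' @param path YAML file path.
#' @return A [cohort_config()] object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(cohort_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s (allowed: %s)",
                 paste(unknown, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  defaults <- formals(cohort_config)
  args <- raw
  # merge partial nested sections over the documented defaults
  for (sec in c("noise", "task_amp", "covariates", "scores", "effects")) {
    if (!is.null(raw[[sec]])) {
      args[[sec]] <- utils::modifyList(eval(defaults[[sec]]), raw[[sec]])
    }
  }
  if (!is.null(raw$group_sizes)) args$group_sizes <- unlist(raw$group_sizes)
  do.call(cohort_config, args)
}
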