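# Declarative configuration files replacing the interactive steps of a
# point-and-click workflow: transformation specs, positivity thresholds.

#' Read per-channel transformation specs from YAML
#'
#' The file maps channel labels to `{kind, params}` blocks, e.g.
#' `CD3: {kind: arcsinh, params: {a: 0, b: 0.2, c: 0}}`.
#'
#' @param path Path to the YAML file.
#' @return Named list of [transform_spec()] objects.
#' @export
read_transform_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(x) {
    do.call(transform_spec, c(list(kind = x$kind), x$params))
  })
}

#' Write per-channel transformation specs to YAML
#'
#' The summary counterpart of [read_transform_config()]; records every
#' channel's transformation kind and parameters so the exact same
#' transformation can be re-applied to further samples.
#'
#' @param specs Named list of [transform_spec()] objects.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_transform_config <- function(specs, path) {
  yaml::write_yaml(lapply(specs, function(sp)
    list(kind = sp$kind, params = sp$params)), path)
  invisible(path)
}

#' Read per-channel positivity thresholds
#'
#' TSV with columns `channel` and `cutoff`.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of thresholds.
#' @export
read_thresholds <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("channel", "cutoff") %in% names(tab))) {
    cp_stop("cp_io_error", "thresholds file must have columns channel, cutoff")
  }
  stats::setNames(tab$cutoff, tab$channel)
}
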