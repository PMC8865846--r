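#' Write / read configurations as YAML
#'
#' Serializes any of the package's configuration objects
#' ([exploration_config()], [network_config()], [lfp_config()],
#' [stdp_kernel()]) to YAML and restores it with its class, so pipeline
#' stages can be re-run from files. Nested sub-configurations (e.g. the
#' exploration config inside an [experiment_config()]) are not serialized;
#' store them in their own files.
#'
#' @param config A configuration object (a classed list of plain values).
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  obj <- unclass(config)
  obj <- obj[!vapply(obj, is.list, logical(1)) |
               names(obj) %in% c("scale_grid", "seeds")]
  obj$.class <- class(config)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  if (!is.null(obj$n_cells)) obj$n_cells <- as.integer(obj$n_cells)
  structure(obj, class = cls)
}
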