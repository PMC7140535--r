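# Calibration constants: every tunable that is neither a literature value
# from the entity table nor a drug label figure is read from one YAML file
# so nothing is hard-coded in the rule handlers.

#' Load calibration constants
#'
#' @param path YAML file of calibration constants; default the bundled file.
#' @return Named list of constants.
#' @export
load_calibration <- function(path) {
  cal <- yaml::read_yaml(path)
  req <- c("p_capture_apc", "p_div", "p_ingress", "mbp_per_death",
           "treg_tonic", "k_suppression", "apoptosis_p_min",
           "impairment_base", "ms_reference_impairment")
  miss <- setdiff(req, names(cal))
  if (length(miss)) stop("calibration file lacks: ", paste(miss, collapse = ", "))
  cal
}

#' @rdname load_calibration
#' @export
default_calibration <- function() {
  if (is.null(.pkg$cal)) {
    .pkg$cal <- load_calibration(system.file("extdata", "calibration.yaml",
                                             package = "mssim"))
  }
  .pkg$cal
}
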