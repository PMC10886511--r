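# YAML round-tripping of the tunable configuration surface.

#' Write a configuration to YAML
#'
#' Serializes any of the package's configuration objects (encoder gains,
#' Izhikevich parameters, decoder, plant, culture, CWT, coherence or
#' classifier configurations) to a YAML file.
#'
#' @param config a configuration object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  obj <- unclass(config)
  obj$.class <- class(config)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a configuration written by [write_config_yaml()]
#'
#' @param path YAML file.
#' @return the configuration object, re-validated through its constructor.
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  ctor <- switch(cls,
    izhikevich_params = izhikevich_params,
    encoder_gains = encoder_gains,
    decoder_config = decoder_config,
    plant_config = plant_config,
    culture_config = culture_config,
    cwt_config = cwt_config,
    coherence_config = coherence_config,
    classifier_config = classifier_config,
    stop("unknown configuration class: ", cls, call. = FALSE))
  keep <- intersect(names(obj), names(formals(ctor)))
  do.call(ctor, obj[keep])
}
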