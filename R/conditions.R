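# classed conditions so callers/tests can distinguish failure modes
stop_zfsocial <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(paste0("zfsocial_", class),
                                             "zfsocial_error", "error")))
}

warn_zfsocial <- function(class, ...) {
  warning(warningCondition(paste0(...), class = c(paste0("zfsocial_", class),
                                                  "zfsocial_warning", "warning")))
}
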