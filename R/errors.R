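#' @keywords internal
mux_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mux_error")))
}

mux_schema_error     <- function(msg) mux_error(msg, "mux_schema_error")
mux_validation_error <- function(msg) mux_error(msg, "mux_validation_error")
mux_unit_error       <- function(msg) mux_error(msg, "mux_unit_error")
mux_config_error     <- function(msg) mux_error(msg, "mux_config_error")

#' Log a message with module, level and timestamp
#'
#' All user-visible diagnostics (including every drug demotion) flow through
#' this helper so that no scheduling decision is silent.
#'
#' @param module character scalar naming the emitting module.
#' @param level one of `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param msg message text.
#' @keywords internal
mux_log <- function(module, level, msg) {
  message(sprintf("[%s] [%s] [%s] %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), module, level, msg))
}
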