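# Shared condition helpers and small validators.

gs_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "gradsift_error"),
                      call = call))
}

gs_format_error <- function(msg) gs_error(msg, "gradsift_format_error")
gs_integrity_error <- function(msg) gs_error(msg, "gradsift_integrity_error")
gs_parameter_error <- function(msg) gs_error(msg, "gradsift_parameter_error")

#' @keywords internal
fraction_labels <- function() sprintf("F%02d", 1:20)

value_columns <- function() c(fraction_labels(), "P")

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    gs_parameter_error(sprintf("'%s' must be a single positive finite number", name))
  invisible(x)
}

# seeds fed to set.seed() must stay below .Machine$integer.max
mix_seed <- function(seed, stream, index = 0L) {
  (as.double(seed) * 48271 + stream * 30269 + index * 65537) %% 2147483647
}
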