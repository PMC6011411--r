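# internal helpers

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

abort_schema <- function(msg) {
  rlang::abort(msg, class = "ethnomarket_schema_error")
}

abort_vocabulary <- function(msg) {
  rlang::abort(msg, class = "ethnomarket_vocabulary_error")
}

abort_parameter <- function(msg) {
  rlang::abort(msg, class = "ethnomarket_parameter_error")
}

abort_sizing <- function(msg) {
  rlang::abort(msg, class = "ethnomarket_sizing_error")
}

abort_dimension <- function(msg) {
  rlang::abort(msg, class = "ethnomarket_dimension_error")
}

# ailment labels are compared case-insensitively after whitespace trimming
normalize_label <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}
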