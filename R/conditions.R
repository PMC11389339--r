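# Classed conditions so callers (and tests) can distinguish failure modes.
# schema: malformed table content; referential: id cross-references;
# lookup: unknown id; domain: value outside its mathematical domain;
# config: invalid generator/pipeline configuration.

abort_schema <- function(msg) {
  rlang::abort(msg, class = "equileague_schema_error")
}

abort_referential <- function(msg) {
  rlang::abort(msg, class = "equileague_referential_error")
}

abort_lookup <- function(msg) {
  rlang::abort(msg, class = "equileague_lookup_error")
}

abort_domain <- function(msg) {
  rlang::abort(msg, class = "equileague_domain_error")
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "equileague_config_error")
}

warn_degenerate <- function(msg) {
  rlang::warn(msg, class = "equileague_degenerate_warning")
}
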