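## Structured condition system.  Every domain error is a classed condition
## inheriting from "tw_error" so callers (and the CLI) can branch on the
## class rather than matching message text.

twCondition <- function(class, message, data = list(),
                        base = c(class, "tw_error", "error", "condition")) {
  structure(class = base, list(message = message, call = sys.call(-2), data = data))
}

twStop <- function(class, fmt, ..., data = list()) {
  stop(twCondition(class, sprintf(fmt, ...), data = data))
}

twWarn <- function(class, fmt, ..., data = list()) {
  warning(structure(
    class = c(class, "tw_warning", "warning", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1), data = data)
  ))
}

## condition classes used across the package:
##   tw_not_found, tw_unresolved_reference, tw_duplicate_name, tw_empty_name,
##   tw_bad_kind, tw_dependency_exists, tw_immutable_field, tw_unknown_layer,
##   tw_cycle, tw_no_path, tw_empty_input, tw_no_formatter, tw_parse_error,
##   tw_loader_failure, tw_missing_attribute, tw_bad_path, tw_type_mismatch,
##   tw_duplicate_protocol, tw_no_worker, tw_missing_input, tw_not_finished,
##   tw_stage_failed, tw_no_location, tw_schema_error, tw_bad_spec
## warning classes: tw_lossy

`%||%` <- function(a, b) if (is.null(a)) b else a
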