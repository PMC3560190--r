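# Structured error conditions shared across the package.
#
# Three classes distinguish the failure modes a pipeline driver cares about:
#   ct_input_error - a file is missing or its content violates a semantic rule
#                    (duplicate species, conflicting cluster assignment, ...)
#   ct_parse_error - a line of a file cannot be decoded (wrong column count,
#                    non-integer coordinate, bad strand); carries line numbers
#   ct_usage_error - the caller combined arguments incorrectly

ct_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ct_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ct_input_error <- function(msg, ...) ct_stop("ct_input_error", msg, ...)
ct_parse_error <- function(msg, line = NA_integer_, ...) {
  ct_stop("ct_parse_error", msg, line = line, ...)
}
ct_usage_error <- function(msg, ...) ct_stop("ct_usage_error", msg, ...)
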