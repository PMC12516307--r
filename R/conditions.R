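# Structured condition constructors. All decode failures share the parent
# class "dnf_decode_error" so callers can catch corruption and version
# problems together; validation failures carry the full violation table.

dnf_error <- function(message, class, ...) {
  structure(
    class = c(class, "dnf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_validation <- function(violations) {
  msg <- paste0(
    "annotation is not valid (", nrow(violations), " violation",
    if (nrow(violations) == 1L) "" else "s", "):\n",
    paste0("  - ", violations$path, ": ", violations$message, collapse = "\n")
  )
  stop(dnf_error(msg, c("dnf_validation_error"), violations = violations))
}

stop_parse <- function(message, line = NA_integer_, column = NA_integer_) {
  loc <- if (!is.na(line)) sprintf(" (line %d, column %d)", line, column) else ""
  stop(dnf_error(paste0("dngf parse error", loc, ": ", message),
                 "dngf_parse_error", line = line, column = column))
}

stop_version <- function(message, found = NULL, supported = NULL) {
  stop(dnf_error(message, c("dnf_version_error", "dnf_decode_error"),
                 found = found, supported = supported))
}

stop_integrity <- function(message, record = NULL) {
  stop(dnf_error(message, c("dnf_integrity_error", "dnf_decode_error"),
                 record = record))
}
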