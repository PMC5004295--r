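# Shared condition helpers. Every user-facing failure is signalled with a
# subclass of "crykit_error" so callers (and the CLI) can map conditions to
# exit codes without string matching.

cry_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "crykit_error", "error", "condition"),
    list(message = message, ...)
  ))
}

cry_warn <- function(message, class = "crykit_warning") {
  warning(structure(
    class = c(class, "crykit_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# 20 standard residues plus the tolerated extended letters
STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
EXTENDED_AA <- c(STANDARD_AA, "B", "Z", "X", "U")

valid_sequence_letters <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  chars[!chars %in% EXTENDED_AA]
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)
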