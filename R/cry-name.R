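#' Parse a Cry protein name into its nomenclature ranks
#'
#' Cry proteins are named by a four-rank nomenclature: a primary numeric
#' rank, a secondary uppercase letter, a tertiary lowercase letter and a
#' quaternary number (e.g. `Cry1Aa1`). Later ranks are only ever present
#' when all earlier ranks are: `Cry5B` is valid, `Cry1A1` is not.
#'
#' @param name A single protein name beginning with `"Cry"`
#'   (case-sensitive), e.g. `"Cry1Aa1"`, `"Cry5B"`, `"Cry6Aa"`.
#'
#' @return An object of class `cry_name`: a list with `primary`,
#'   `secondary`, `tertiary`, `quaternary` (each `NA` when absent) and
#'   `raw`, the original string. [format_cry_name()] reproduces `raw`
#'   exactly.
#'
#' @examples
#' parse_cry_name("Cry1Aa1")
#' parse_cry_name("Cry5B")
#' @seealso [format_cry_name()]
#' @export
parse_cry_name <- function(name) {
  if (!is_string(name) || !nzchar(name)) {
    cry_abort("protein name must be a non-empty string", "crykit_parse_error")
  }
  if (!startsWith(name, "Cry")) {
    cry_abort(
      sprintf("'%s' is not a Cry protein name: missing 'Cry' prefix", name),
      "crykit_parse_error"
    )
  }
  # nested optional groups enforce left-to-right rank population
  pattern <- "^Cry([0-9]+)(?:([A-Z])(?:([a-z])([0-9]+)?)?)?$"
  m <- regmatches(name, regexec(pattern, name))[[1]]
  if (length(m) == 0L) {
    cry_abort(
      sprintf(
        "cannot parse Cry name '%s': ranks after 'Cry%s' violate the number/UPPER/lower/number grammar",
        name, sub("^Cry([0-9]*).*$", "\\1", name)
      ),
      "crykit_parse_error"
    )
  }
  structure(
    list(
      primary    = as.integer(m[2]),
      secondary  = if (nzchar(m[3])) m[3] else NA_character_,
      tertiary   = if (nzchar(m[4])) m[4] else NA_character_,
      quaternary = if (nzchar(m[5])) as.integer(m[5]) else NA_integer_,
      raw        = name
    ),
    class = "cry_name"
  )
}

#' Format a parsed Cry name back to its string form
#'
#' @param x A `cry_name` from [parse_cry_name()].
#' @return The protein name string; for any parseable name this equals the
#'   string originally parsed (round-trip identity).
#' @export
format_cry_name <- function(x) {
  stopifnot(inherits(x, "cry_name"))
  paste0(
    "Cry", x$primary,
    if (!is.na(x$secondary)) x$secondary else "",
    if (!is.na(x$tertiary)) x$tertiary else "",
    if (!is.na(x$quaternary)) x$quaternary else ""
  )
}

#' @export
format.cry_name <- function(x, ...) format_cry_name(x)

#' @export
print.cry_name <- function(x, ...) {
  cat(sprintf(
    "<cry_name> %s (primary=%d secondary=%s tertiary=%s quaternary=%s)\n",
    x$raw, x$primary, x$secondary, x$tertiary, x$quaternary
  ))
  invisible(x)
}
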