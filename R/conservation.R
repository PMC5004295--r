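# Residue conservation classes follow the Clustal X consensus-symbol
# convention: a substitution within one "strong" physicochemical group is a
# conserved mutation (the ':' symbol), one within only a "weak" group is a
# semi-conserved mutation ('.'), anything else — including any gap — is
# non-conserved. Strong membership is checked before weak.

STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                   "HY", "FYW")
WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SDEQK",
                 "NDEQHK", "NEQHRK", "FVLIM", "HFY")

COLUMN_CLASSES <- c("CONSERVED", "CONSERVED_MUTATION",
                    "SEMI_CONSERVED_MUTATION", "NON_CONSERVED")

group_members <- function(groups) lapply(groups, function(g) strsplit(g, "")[[1]])
.strong <- group_members(STRONG_GROUPS)
.weak <- group_members(WEAK_GROUPS)

share_group <- function(a, b, groups) {
  for (g in groups) if (a %in% g && b %in% g) return(TRUE)
  FALSE
}

#' Classify one alignment column of a protein pair
#'
#' Given the two characters occupying an alignment column, decide its
#' conservation class:
#' * identical standard residues: `CONSERVED` (C);
#' * residues sharing a strong group: `CONSERVED_MUTATION` (CM);
#' * residues sharing only a weak group: `SEMI_CONSERVED_MUTATION` (SCM);
#' * everything else — including a residue against a gap, and identical
#'   nonstandard letters (which belong to no group): `NON_CONSERVED` (NC).
#'
#' Columns where both rows carry a gap are rejected; they must be dropped
#' before classification (they only arise when more than two sequences
#' were aligned together).
#'
#' @param a,b A residue letter or `'-'` each.
#' @return A `column_class` list with `value` (one of the four classes)
#'   and `gap_involved` (`TRUE` only with `value == "NON_CONSERVED"`).
#' @examples
#' classify_column("A", "A")  # CONSERVED
#' classify_column("H", "Y")  # CONSERVED_MUTATION (strong group HY)
#' classify_column("A", "-")  # NON_CONSERVED, gap involved
#' @export
classify_column <- function(a, b) {
  for (x in c(a, b)) {
    if (!is_string(x) || !(x %in% EXTENDED_AA || x == "-")) {
      cry_abort(
        sprintf("'%s' is neither a residue letter nor a gap", x),
        "crykit_argument_error"
      )
    }
  }
  if (a == "-" && b == "-") {
    cry_abort("all-gap columns must be dropped before classification",
              "crykit_argument_error")
  }
  structure(
    list(value = classify_chars(a, b), gap_involved = (a == "-" || b == "-")),
    class = "column_class"
  )
}

# scalar classification without validation; used by the vectorized path
classify_chars <- function(a, b) {
  if (a == "-" || b == "-") return("NON_CONSERVED")
  if (a == b) {
    return(if (a %in% STANDARD_AA) "CONSERVED" else "NON_CONSERVED")
  }
  if (share_group(a, b, .strong)) return("CONSERVED_MUTATION")
  if (share_group(a, b, .weak)) return("SEMI_CONSERVED_MUTATION")
  "NON_CONSERVED"
}

classify_columns <- function(chars_a, chars_b) {
  mapply(classify_chars, chars_a, chars_b, USE.NAMES = FALSE)
}

#' Map an alignment column to its ungapped sequence position
#'
#' @param gapped_row A gapped alignment row.
#' @param column 1-based alignment column.
#' @return The 1-based position of the residue in the ungapped sequence
#'   (the count of non-gap characters in `row[1..column]`), or `NA` when
#'   the column holds a gap in this row.
#' @examples
#' column_to_seq_position("--AB-C", 3)  # 1
#' column_to_seq_position("--AB-C", 5)  # NA (gap)
#' @export
column_to_seq_position <- function(gapped_row, column) {
  if (!is_string(gapped_row) || !nzchar(gapped_row)) {
    cry_abort("gapped_row must be a non-empty string", "crykit_argument_error")
  }
  column <- as.integer(column)
  if (is.na(column) || column < 1L || column > nchar(gapped_row)) {
    cry_abort(
      sprintf("column %s out of range 1..%d", column, nchar(gapped_row)),
      "crykit_argument_error"
    )
  }
  chars <- strsplit(gapped_row, "")[[1]]
  if (chars[column] == "-") return(NA_integer_)
  sum(chars[seq_len(column)] != "-")
}
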