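#' Describe one structural domain region of a Cry protein
#'
#' Three-domain Cry toxins carry up to three structural domains (Domain I:
#' pore formation; Domains II/III: receptor recognition and binding).
#' Positions are 1-based inclusive residue coordinates on the ungapped
#' protein sequence, matching NCBI region features.
#'
#' @param index Domain number, 1, 2 or 3.
#' @param start,end 1-based inclusive residue positions, `start <= end`.
#' @return A `domain_region` list with `index`, `start`, `end` and the
#'   derived `length = end - start + 1`.
#' @export
domain_region <- function(index, start, end) {
  index <- as.integer(index); start <- as.integer(start); end <- as.integer(end)
  if (is.na(index) || !index %in% 1:3) {
    cry_abort("domain index must be 1, 2 or 3", "crykit_argument_error")
  }
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    cry_abort(
      sprintf("domain %d positions must satisfy 1 <= start <= end (got %s..%s)",
              index, start, end),
      "crykit_argument_error"
    )
  }
  structure(
    list(index = index, start = start, end = end,
         length = end - start + 1L),
    class = "domain_region"
  )
}

#' Construct a Cry protein record
#'
#' The central container for one protein: its parsed nomenclature name,
#' identifiers, amino acid sequence, up to three domain regions, the insect
#' orders it affects, literature references and any deposited structural
#' model ids. Constructors do not validate the scientific invariants; run
#' [validate_record()] to obtain a list of violations.
#'
#' @param name A `cry_name` (see [parse_cry_name()]) or a name string.
#' @param gi NCBI GI number as a string.
#' @param accession NCBI accession.
#' @param protein_id Versioned protein id (e.g. `"AAA22353.1"`).
#' @param nucleotide_id Optional id of the encoding nucleotide record.
#' @param sequence Upper-case amino acid sequence (IUPAC one-letter; the
#'   extended letters B, Z, X, U are tolerated).
#' @param domains List of 0-3 [domain_region()] objects.
#' @param affected_orders Character vector of insect-order names.
#' @param references List of lists with `title`, `authors`, `citation`.
#' @param model_ids Character vector of structural model ids.
#' @return A `protein_record` object.
#' @export
protein_record <- function(name, gi = "", accession = "", protein_id = "",
                           nucleotide_id = NA_character_, sequence = "",
                           domains = list(), affected_orders = character(),
                           references = list(), model_ids = character()) {
  if (is.character(name)) name <- parse_cry_name(name)
  stopifnot(inherits(name, "cry_name"))
  structure(
    list(
      name = name, gi = as.character(gi), accession = as.character(accession),
      protein_id = as.character(protein_id),
      nucleotide_id = if (is.null(nucleotide_id)) NA_character_ else as.character(nucleotide_id),
      sequence = toupper(as.character(sequence)),
      domains = domains,
      affected_orders = as.character(affected_orders),
      references = references,
      model_ids = as.character(model_ids)
    ),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  gi=%s accession=%s  %d aa, %d domain(s)\n",
              x$name$raw, x$gi, x$accession, nchar(x$sequence),
              length(x$domains)))
  invisible(x)
}

#' Validate a protein record against its invariants
#'
#' Validation never throws: it returns a character vector of violation
#' descriptions, empty when the record is sound. Checked rules: non-empty
#' sequence; sequence alphabet (20 standard residues plus B/Z/X/U); at most
#' three domain regions; every region within `1..nchar(sequence)`; regions
#' non-overlapping and ordered by index and by start.
#'
#' @param record A [protein_record()].
#' @return Character vector of violations (empty if valid).
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  violations <- character()
  len <- nchar(record$sequence)

  if (len == 0L) {
    violations <- c(violations, "sequence: must be non-empty for a processed record")
  } else {
    bad <- unique(valid_sequence_letters(record$sequence))
    if (length(bad) > 0L) {
      violations <- c(violations, sprintf(
        "sequence: invalid letter(s) %s (allowed: 20 standard residues plus B, Z, X, U)",
        paste0("'", bad, "'", collapse = ", ")
      ))
    }
  }

  doms <- record$domains
  if (length(doms) > 3L) {
    violations <- c(violations, sprintf(
      "domains: %d regions given but a Cry toxin carries at most 3", length(doms)
    ))
  }
  for (d in doms) {
    if (!inherits(d, "domain_region")) {
      violations <- c(violations, "domains: entry is not a domain_region")
      next
    }
    if (len > 0L && d$end > len) {
      violations <- c(violations, sprintf(
        "domains: domain %d bounds %d..%d exceed sequence length %d",
        d$index, d$start, d$end, len
      ))
    }
  }
  ok <- vapply(doms, inherits, logical(1), what = "domain_region")
  doms <- doms[ok]
  if (length(doms) >= 2L) {
    idx <- vapply(doms, `[[`, integer(1), "index")
    starts <- vapply(doms, `[[`, integer(1), "start")
    ends <- vapply(doms, `[[`, integer(1), "end")
    if (is.unsorted(idx, strictly = TRUE) || is.unsorted(starts, strictly = TRUE)) {
      violations <- c(violations,
                      "domains: regions must be ordered by index and by start")
    }
    if (any(starts[-1] <= ends[-length(ends)])) {
      violations <- c(violations, "domains: regions overlap")
    }
  }
  violations
}
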