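ALIGNMENT_ALGORITHMS <- c("clustalo", "clustalw", "muscle", "mafft",
                          "builtin-nw", "file")

#' Construct an alignment result
#'
#' Container for a gapped alignment: equal-length rows over the amino acid
#' alphabet plus `'-'`, the ids they belong to, which algorithm produced
#' them with what parameters, and (optionally) the region selector the
#' input sequences were taken from.
#'
#' @param ids Character vector of sequence identifiers.
#' @param rows Character vector of gapped rows, all the same width.
#' @param algorithm One of `"clustalo"`, `"clustalw"`, `"muscle"`,
#'   `"mafft"`, `"builtin-nw"` or `"file"` (for alignments read from disk).
#' @param parameters Named list/character map of free-form parameters.
#' @param selector Optional [region_selector()].
#' @return An `alignment_result` object.
#' @export
alignment_result <- function(ids, rows, algorithm = "file",
                             parameters = list(), selector = NULL) {
  ids <- as.character(ids); rows <- toupper(as.character(rows))
  if (length(ids) != length(rows) || length(ids) < 2L) {
    cry_abort("an alignment needs >= 2 rows with matching ids",
              "crykit_format_error")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L || widths[1] < 1L) {
    cry_abort(
      sprintf("alignment rows must share one positive width (got %s)",
              paste(widths, collapse = ", ")),
      "crykit_format_error"
    )
  }
  if (!algorithm %in% ALIGNMENT_ALGORITHMS) {
    cry_abort(sprintf("unknown algorithm '%s'", algorithm),
              "crykit_argument_error")
  }
  structure(
    list(ids = ids, rows = rows, algorithm = algorithm,
         parameters = parameters, selector = selector),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d sequences x %d columns (%s)\n",
              length(x$ids), nchar(x$rows[1]), x$algorithm))
  for (i in seq_along(x$ids)) {
    row <- x$rows[i]
    cat(sprintf("  %-20s %s%s\n", x$ids[i],
                substr(row, 1, 50), if (nchar(row) > 50) "..." else ""))
  }
  invisible(x)
}

#' Read an alignment from aligned FASTA or Clustal text
#'
#' Clustal consensus/conservation symbol lines (`* : .`) are discarded on
#' read: conservation is always recomputed by [analyze_pair()], never
#' trusted from the file.
#'
#' @param x Path to an alignment file, or the alignment text itself.
#' @param format `"fasta"` or `"clustal"`.
#' @return An [alignment_result()] with `algorithm = "file"`.
#' @export
read_alignment <- function(x, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!is_string(x)) {
    cry_abort("x must be a path or alignment text", "crykit_argument_error")
  }
  is_path <- !grepl("\n", x) && file.exists(x)
  text <- if (is_path) paste(readLines(x, warn = FALSE), collapse = "\n") else x
  if (!nzchar(trimws(text))) {
    cry_abort("empty alignment document", "crykit_format_error")
  }
  parsed <- if (format == "fasta") parse_fasta_text(text)
            else parse_clustal_text(text)
  alignment_result(ids = parsed$ids, rows = parsed$rows, algorithm = "file")
}

parse_fasta_text <- function(text) {
  path <- tempfile(fileext = ".fasta")
  on.exit(unlink(path))
  writeLines(text, path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) cry_abort(
      sprintf("cannot parse FASTA alignment: %s", conditionMessage(e)),
      "crykit_format_error"
    )
  )
  if (length(set) == 0L) {
    cry_abort("no FASTA records found", "crykit_format_error")
  }
  list(ids = names(set), rows = as.character(set))
}

parse_clustal_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) > 0L && grepl("^(CLUSTAL|MUSCLE)", lines[1])) {
    lines <- lines[-1]
  }
  pieces <- list()
  order <- character()
  for (line in lines) {
    if (!nzchar(trimws(line))) next
    # conservation lines hold only the consensus symbols and whitespace
    if (grepl("^\\s", line) || !grepl("^\\S+\\s+\\S", line)) next
    m <- regmatches(line, regexec("^(\\S+)\\s+([A-Za-z-]+)(\\s+\\d+)?\\s*$",
                                  line))[[1]]
    if (length(m) == 0L) next
    id <- m[2]; chunk <- m[3]
    if (!id %in% order) order <- c(order, id)
    pieces[[id]] <- paste0(pieces[[id]] %||% "", chunk)
  }
  if (length(order) == 0L) {
    cry_abort("no sequence lines found in Clustal document",
              "crykit_format_error")
  }
  list(ids = order, rows = unlist(pieces[order], use.names = FALSE))
}

#' Write an alignment as aligned FASTA
#'
#' @param result An [alignment_result()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(result, path) {
  stopifnot(inherits(result, "alignment_result"))
  write_fasta(setNames(result$rows, result$ids), path)
}
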