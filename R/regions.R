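#' Select a protein region: the complete sequence or one domain
#'
#' @param kind `"complete"` or `"domain"`.
#' @param domain_index Domain number 1-3; required (and only allowed)
#'   when `kind == "domain"`.
#' @return A `region_selector` object.
#' @examples
#' region_selector("complete")
#' region_selector("domain", 2)
#' @export
region_selector <- function(kind = c("complete", "domain"), domain_index = NULL) {
  kind <- match.arg(kind)
  if (kind == "domain") {
    if (is.null(domain_index) || !as.integer(domain_index) %in% 1:3) {
      cry_abort("a domain selector needs domain_index 1, 2 or 3",
                "crykit_argument_error")
    }
    domain_index <- as.integer(domain_index)
  } else if (!is.null(domain_index)) {
    cry_abort("domain_index is only meaningful with kind = 'domain'",
              "crykit_argument_error")
  }
  structure(list(kind = kind, domain_index = domain_index),
            class = "region_selector")
}

region_label <- function(selector) {
  if (selector$kind == "complete") "complete"
  else paste0("domain", selector$domain_index)
}

# short form used in file names and CLI flags: complete|d1|d2|d3
region_short <- function(selector) {
  if (selector$kind == "complete") "complete"
  else paste0("d", selector$domain_index)
}

#' Parse a region flag value ("complete", "d1", "d2", "d3")
#' @param x Flag value.
#' @return A [region_selector()].
#' @export
parse_region_flag <- function(x) {
  switch(tolower(x),
    complete = region_selector("complete"),
    d1 = region_selector("domain", 1), d2 = region_selector("domain", 2),
    d3 = region_selector("domain", 3),
    cry_abort(sprintf("unknown region '%s' (use complete, d1, d2 or d3)", x),
              "crykit_argument_error")
  )
}

#' Extract the selected region of a protein record
#'
#' @param record A [protein_record()].
#' @param selector A [region_selector()].
#' @return The amino acid string of the region: the full sequence for
#'   `"complete"`, or `sequence[start..end]` (1-based inclusive) of the
#'   selected domain.
#' @export
extract_region <- function(record, selector) {
  stopifnot(inherits(record, "protein_record"),
            inherits(selector, "region_selector"))
  if (selector$kind == "complete") return(record$sequence)
  k <- selector$domain_index
  for (d in record$domains) {
    if (d$index == k) return(substr(record$sequence, d$start, d$end))
  }
  cry_abort(
    sprintf("%s carries no Domain %d annotation", record$name$raw, k),
    "crykit_region_error"
  )
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Generate per-region FASTA files for a set of protein records
#'
#' For each record with full domain annotation, four files are written:
#' the complete sequence and one per domain. Records with fewer than three
#' annotated domains yield one file for the complete sequence plus one per
#' available domain, with a warning. Headers read
#' `>{name}|{accession}|{region label}`; sequences are wrapped at 60
#' columns with LF line endings.
#'
#' @param records List of [protein_record()] objects.
#' @param out_dir Writable output directory (created if missing).
#' @return Character vector of written file paths.
#' @export
generate_fasta_files <- function(records, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) cry_abort(sprintf("cannot create output directory %s", out_dir),
                       "crykit_io_error")
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    cry_abort(sprintf("output directory %s is not writable", out_dir),
              "crykit_io_error")
  }
  paths <- character()
  for (r in records) {
    selectors <- c(
      list(region_selector("complete")),
      lapply(r$domains, function(d) region_selector("domain", d$index))
    )
    if (length(r$domains) < 3L) {
      cry_warn(sprintf(
        "%s has %d of 3 domain annotations; writing %d file(s) instead of 4",
        r$name$raw, length(r$domains), length(selectors)
      ))
    }
    for (sel in selectors) {
      header <- paste(r$name$raw, r$accession, region_label(sel), sep = "|")
      path <- file.path(out_dir, sprintf(
        "%s_%s.fasta", sanitize_filename(r$name$raw), region_short(sel)))
      write_fasta(setNames(extract_region(r, sel), header), path)
      paths <- c(paths, path)
    }
  }
  paths
}

#' Filter protein records by affected insect order
#'
#' A record is retained when its affected orders intersect the wanted set
#' (compared case-insensitively). An empty wanted set means "no filter":
#' all records are retained.
#'
#' @param records List of [protein_record()] objects.
#' @param wanted_orders Character vector of insect-order names.
#' @return The retained records, in input order.
#' @export
filter_by_orders <- function(records, wanted_orders = character()) {
  if (length(wanted_orders) == 0L) return(records)
  wanted <- tolower(trimws(wanted_orders))
  Filter(function(r) any(tolower(trimws(r$affected_orders)) %in% wanted),
         records)
}
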