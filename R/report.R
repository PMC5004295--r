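# Report rendering. Four sections mirror the analysis workflow:
#   A  protein data (ids, total length, domain sizes)
#   B  structure diagrams (domain disposition within the full sequence)
#   C  conservation statistics (C, CM, SCM, C+CM, NC with percentages)
#   D  full alignment rendering with per-column class marks
# plus the free-text observation supplied by the analyst.

CLASS_MARKS <- c(CONSERVED = "*", CONSERVED_MUTATION = ":",
                 SEMI_CONSERVED_MUTATION = ".", NON_CONSERVED = " ")

protein_block_lines <- function(record) {
  dom_size <- function(k) {
    for (d in record$domains) if (d$index == k) return(as.character(d$length))
    "not annotated"
  }
  c(
    sprintf("name: %s", record$name$raw),
    sprintf("accession: %s", record$accession),
    sprintf("protein_id: %s", record$protein_id),
    sprintf("nucleotide_id: %s",
            if (is.na(record$nucleotide_id)) "unavailable" else record$nucleotide_id),
    sprintf("total_length: %d", nchar(record$sequence)),
    sprintf("domain1_length: %s", dom_size(1)),
    sprintf("domain2_length: %s", dom_size(2)),
    sprintf("domain3_length: %s", dom_size(3))
  )
}

structure_diagram_lines <- function(record, width = 60L) {
  len <- nchar(record$sequence)
  bar <- rep(".", width)
  labels <- character()
  for (d in record$domains) {
    from <- max(1L, round(d$start / len * width))
    to <- max(from, round(d$end / len * width))
    bar[from:to] <- as.character(d$index)
    labels <- c(labels, sprintf("domain %d: %d..%d", d$index, d$start, d$end))
  }
  c(
    sprintf("%s  (1..%d)", record$name$raw, len),
    paste0("[", paste(bar, collapse = ""), "]"),
    if (length(labels) > 0) labels else "no domain annotations"
  )
}

alignment_diagram_lines <- function(analysis, block = 60L) {
  aln <- analysis$alignment
  r1 <- aln$rows[analysis$indices[1]]
  r2 <- aln$rows[analysis$indices[2]]
  n <- nchar(r1)
  marks <- vapply(seq_len(n), function(i) {
    a <- substr(r1, i, i); b <- substr(r2, i, i)
    if (a == "-" && b == "-") return(" ")
    CLASS_MARKS[[classify_chars(a, b)]]
  }, character(1))
  marks <- paste(marks, collapse = "")
  lines <- character()
  for (from in seq(1L, n, by = block)) {
    to <- min(from + block - 1L, n)
    lines <- c(lines,
      sprintf("%-12s %s %d", substr(analysis$ids[1], 1, 12), substr(r1, from, to), to),
      sprintf("%-12s %s", substr(analysis$ids[2], 1, 12), substr(r2, from, to)),
      sprintf("%-12s %s", "", substr(marks, from, to)),
      "")
  }
  lines
}

statistics_lines <- function(stats) {
  pct <- stats$percentages
  c(
    sprintf("alignment_columns: %d", stats$c + stats$cm + stats$scm + stats$nc),
    sprintf("residues_protein_1: %d", stats$length_1),
    sprintf("residues_protein_2: %d", stats$length_2),
    "statistic\tcount\tpct_protein_1\tpct_protein_2",
    sprintf("%s\t%d\t%.2f\t%.2f", pct$statistic, pct$count, pct$pct_1, pct$pct_2)
  )
}

check_report_consistency <- function(record_1, record_2, analysis) {
  aln <- analysis$alignment
  got <- list(ungap(aln$rows[analysis$indices[1]]),
              ungap(aln$rows[analysis$indices[2]]))
  # when the alignment records its region selector, hold it to that; an
  # alignment re-read from disk carries none, so accept any region of the
  # records (complete or one domain), the same for both
  candidates <- if (!is.null(aln$selector)) {
    list(aln$selector)
  } else {
    c(list(region_selector("complete")),
      lapply(intersect(
        vapply(record_1$domains, `[[`, integer(1), "index"),
        vapply(record_2$domains, `[[`, integer(1), "index")
      ), function(k) region_selector("domain", k)))
  }
  for (sel in candidates) {
    expected <- list(extract_region(record_1, sel), extract_region(record_2, sel))
    if (identical(expected, got)) return(invisible(sel))
  }
  cry_abort(
    "analysis was not produced from these two records (aligned regions do not match their sequences)",
    "crykit_consistency_error"
  )
}

#' Render a pairwise analysis report
#'
#' Produces the analysis report in structured text (machine-parseable,
#' see [read_report_statistics()]) or HTML. The report carries: section A,
#' both proteins' name, accession, protein id, nucleotide id, total length
#' and the three domain sizes; section B, a domain-disposition diagram per
#' protein with boundaries and names; section C, the statistics table
#' (C, CM, SCM, C+CM, NC with both percentage columns); section D, the
#' full alignment with per-column class marks; and the analyst's free-text
#' observation.
#'
#' @param record_1,record_2 The two [protein_record()]s that were aligned;
#'   their selected regions must match the analysis (consistency is
#'   checked).
#' @param analysis A [analyze_pair()] result over those records.
#' @param observation Free text to embed in the report.
#' @param format `"text"` (structured text) or `"html"`.
#' @return The report document as a single string.
#' @export
render_report <- function(record_1, record_2, analysis, observation = "",
                          format = c("text", "html")) {
  format <- match.arg(format)
  stopifnot(inherits(analysis, "pair_analysis"))
  check_report_consistency(record_1, record_2, analysis)
  sections <- list(
    "A. protein data" = c(
      "-- protein 1 --", protein_block_lines(record_1),
      "-- protein 2 --", protein_block_lines(record_2)
    ),
    "B. structure diagrams" = c(
      structure_diagram_lines(record_1), "", structure_diagram_lines(record_2)
    ),
    "C. statistics" = statistics_lines(analysis$stats),
    "D. alignment" = alignment_diagram_lines(analysis),
    "observation" = if (nzchar(observation)) observation else "(none)"
  )
  if (format == "text") {
    lines <- c("== crykit pairwise analysis report ==")
    for (title in names(sections)) {
      lines <- c(lines, "", paste0("== ", title, " =="), sections[[title]])
    }
    paste(lines, collapse = "\n")
  } else {
    esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    body <- vapply(names(sections), function(title) {
      paste0("<h2>", esc(title), "</h2>\n<pre>",
             paste(esc(sections[[title]]), collapse = "\n"), "</pre>")
    }, character(1))
    paste0(
      "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
      "<title>Pairwise analysis: ", esc(analysis$ids[1]), " vs ",
      esc(analysis$ids[2]), "</title></head>\n<body>\n",
      "<h1>Pairwise analysis: ", esc(analysis$ids[1]), " vs ",
      esc(analysis$ids[2]), "</h1>\n",
      paste(body, collapse = "\n"), "\n</body></html>\n"
    )
  }
}

#' Parse the statistics section of a structured-text report
#'
#' Round-trip companion of `render_report(format = "text")`: recovers the
#' statistic counts and percentage columns.
#'
#' @param text A structured-text report.
#' @return A tibble with columns `statistic`, `count`, `pct_1`, `pct_2`.
#' @export
read_report_statistics <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  start <- grep("^== C\\. statistics ==$", lines)
  if (length(start) != 1L) {
    cry_abort("no statistics section found", "crykit_format_error")
  }
  rows <- list()
  for (line in lines[-seq_len(start)]) {
    if (grepl("^== ", line)) break
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) == 4L && f[1] != "statistic") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        statistic = f[1], count = as.integer(f[2]),
        pct_1 = as.numeric(f[3]), pct_2 = as.numeric(f[4])
      )
    }
  }
  do.call(rbind, rows)
}
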