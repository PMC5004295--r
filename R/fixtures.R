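# Offline fixture generator. Emits synthetic (clearly non-biological but
# structurally faithful) inputs for every retrieval-stage format, so the
# whole pipeline runs and is testable with no network access: the
# nomenclature HTML table (rows with and without NCBI hyperlinks), minimal
# Entrez GBSet XML (accession, sequence, domain region features,
# references, coded_by link) and the protein-to-orders table. Everything
# is deterministic under a seed.

INSECT_ORDERS <- c("Lepidoptera", "Coleoptera", "Diptera", "Hemiptera",
                   "Hymenoptera", "Rhabditida")

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

random_aa <- function(n) {
  paste(sample(STANDARD_AA, n, replace = TRUE), collapse = "")
}

#' Generate synthetic Cry-like protein records
#'
#' Each record carries a plausible rank name (`Cry<i>Aa1`), synthetic
#' identifiers, a random amino acid sequence of realistic three-domain
#' toxin size (roughly 570-750 residues) and three non-overlapping domain
#' regions (Domain 1 about 200-240 residues after a leader, Domain 2 about
#' 180-220, Domain 3 about 130-160), mimicking the layout of NCBI region
#' features for three-domain Cry toxins.
#'
#' @param n Number of records.
#' @param seed Integer seed; the same seed gives identical records.
#' @return List of [protein_record()] objects.
#' @export
fixture_records <- function(n, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      leader <- sample(40:80, 1)
      d1 <- sample(200:240, 1); l1 <- sample(5:15, 1)
      d2 <- sample(180:220, 1); l2 <- sample(5:15, 1)
      d3 <- sample(130:160, 1); tail <- sample(10:30, 1)
      total <- leader + d1 + l1 + d2 + l2 + d3 + tail
      s1 <- leader + 1L
      s2 <- s1 + d1 + l1
      s3 <- s2 + d2 + l2
      orders <- sort(sample(INSECT_ORDERS, sample(1:2, 1)))
      protein_record(
        name = sprintf("Cry%dAa1", i),
        gi = as.character(900000L + i),
        accession = sprintf("SYN%05d", i),
        protein_id = sprintf("SYN%05d.1", i),
        nucleotide_id = sprintf("SYNNT%05d.1", i),
        sequence = random_aa(total),
        domains = list(
          domain_region(1, s1, s1 + d1 - 1L),
          domain_region(2, s2, s2 + d2 - 1L),
          domain_region(3, s3, s3 + d3 - 1L)
        ),
        affected_orders = orders,
        references = list(list(
          title = sprintf("Synthetic reference for Cry%dAa1", i),
          authors = "Fixture, G.",
          citation = "Synthetic fixtures 1:1-2"
        ))
      )
    })
  })
}

#' Generate a pair of sequences with a controlled number of substitutions
#'
#' Produces a random sequence and a copy with exactly `n_substitutions`
#' positions replaced by a *different* standard residue, so the expected
#' pairwise statistics are computable in closed form: a gapless alignment
#' of the pair has `length - n_substitutions` conserved columns and
#' `n_substitutions` differences.
#'
#' @param length Sequence length.
#' @param n_substitutions Number of substituted positions (0 to `length`).
#' @param seed Integer seed.
#' @return List with `seq_a`, `seq_b` and the sorted substituted
#'   `positions`.
#' @export
fixture_pair <- function(length = 200L, n_substitutions = 10L, seed = 1L) {
  stopifnot(n_substitutions <= length)
  with_seed(seed, {
    a <- strsplit(random_aa(length), "")[[1]]
    b <- a
    positions <- sort(sample.int(length, n_substitutions))
    for (p in positions) {
      b[p] <- sample(setdiff(STANDARD_AA, a[p]), 1)
    }
    list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""),
         positions = positions)
  })
}

#' Generate a random gapped pairwise alignment
#'
#' Emits a two-row alignment with random residues and random gaps, with
#' all-gap columns excluded, for property-style tests of the conservation
#' partition.
#'
#' @param n_cols Number of alignment columns.
#' @param gap_rate Probability that a column carries a gap in one row.
#' @param seed Integer seed.
#' @return An [alignment_result()].
#' @export
fixture_alignment <- function(n_cols = 80L, gap_rate = 0.1, seed = 1L) {
  with_seed(seed, {
    a <- sample(STANDARD_AA, n_cols, replace = TRUE)
    b <- sample(STANDARD_AA, n_cols, replace = TRUE)
    # make a realistic share of identical columns
    same <- stats::runif(n_cols) < 0.5
    b[same] <- a[same]
    gap <- stats::runif(n_cols) < gap_rate
    which_row <- stats::runif(n_cols) < 0.5
    a[gap & which_row] <- "-"
    b[gap & !which_row] <- "-"
    # guarantee at least one residue per row
    if (all(a == "-")) a[1] <- "A"
    if (all(b == "-")) b[1] <- "A"
    alignment_result(
      ids = c("fix_1", "fix_2"),
      rows = c(paste(a, collapse = ""), paste(b, collapse = "")),
      algorithm = "file"
    )
  })
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

nomenclature_html_text <- function(records, linkless) {
  rows <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    cell <- if (linkless[i]) {
      r$accession
    } else {
      sprintf("<a href=\"https://www.ncbi.nlm.nih.gov/protein/%s\">%s</a>",
              r$gi, r$accession)
    }
    sprintf("    <tr><td>%s</td><td>%s</td><td>%s</td></tr>",
            html_escape(r$name$raw), cell,
            html_escape(paste(r$affected_orders, collapse = ", ")))
  }, character(1))
  paste(c(
    "<!DOCTYPE html>",
    "<html><head><title>Bt toxin nomenclature (synthetic fixture)</title></head>",
    "<body>",
    "  <h1>Full toxin list (synthetic fixture)</h1>",
    "  <table>",
    "    <tr><th>Protein Name</th><th>NCBI accession</th><th>Affected orders</th></tr>",
    rows,
    "  </table>",
    "</body></html>"
  ), collapse = "\n")
}

entrez_xml_text <- function(records) {
  entry <- function(r) {
    seq_lower <- tolower(r$sequence)
    regions <- vapply(r$domains, function(d) {
      paste0(
        "      <GBFeature>\n",
        "        <GBFeature_key>Region</GBFeature_key>\n",
        sprintf("        <GBFeature_location>%d..%d</GBFeature_location>\n",
                d$start, d$end),
        "        <GBFeature_intervals>\n",
        sprintf("          <GBInterval><GBInterval_from>%d</GBInterval_from><GBInterval_to>%d</GBInterval_to></GBInterval>\n",
                d$start, d$end),
        "        </GBFeature_intervals>\n",
        "        <GBFeature_quals>\n",
        sprintf("          <GBQualifier><GBQualifier_name>region_name</GBQualifier_name><GBQualifier_value>Domain %d</GBQualifier_value></GBQualifier>\n",
                d$index),
        "        </GBFeature_quals>\n",
        "      </GBFeature>\n"
      )
    }, character(1))
    refs <- vapply(r$references, function(ref) {
      paste0(
        "      <GBReference>\n",
        sprintf("        <GBReference_title>%s</GBReference_title>\n",
                html_escape(ref$title)),
        "        <GBReference_authors>\n",
        sprintf("          <GBAuthor>%s</GBAuthor>\n", html_escape(ref$authors)),
        "        </GBReference_authors>\n",
        sprintf("        <GBReference_journal>%s</GBReference_journal>\n",
                html_escape(ref$citation)),
        "      </GBReference>\n"
      )
    }, character(1))
    paste0(
      "  <GBSeq>\n",
      sprintf("    <GBSeq_locus>%s</GBSeq_locus>\n", r$accession),
      sprintf("    <GBSeq_length>%d</GBSeq_length>\n", nchar(r$sequence)),
      "    <GBSeq_moltype>AA</GBSeq_moltype>\n",
      sprintf("    <GBSeq_definition>pesticidal crystal protein %s (synthetic fixture)</GBSeq_definition>\n",
              r$name$raw),
      sprintf("    <GBSeq_primary-accession>%s</GBSeq_primary-accession>\n",
              r$accession),
      sprintf("    <GBSeq_accession-version>%s</GBSeq_accession-version>\n",
              r$protein_id),
      "    <GBSeq_other-seqids>\n",
      sprintf("      <GBSeqid>gb|%s|</GBSeqid>\n", r$protein_id),
      sprintf("      <GBSeqid>gi|%s</GBSeqid>\n", r$gi),
      "    </GBSeq_other-seqids>\n",
      "    <GBSeq_references>\n", paste(refs, collapse = ""),
      "    </GBSeq_references>\n",
      "    <GBSeq_feature-table>\n", paste(regions, collapse = ""),
      "      <GBFeature>\n",
      "        <GBFeature_key>CDS</GBFeature_key>\n",
      "        <GBFeature_quals>\n",
      sprintf("          <GBQualifier><GBQualifier_name>coded_by</GBQualifier_name><GBQualifier_value>%s:1..%d</GBQualifier_value></GBQualifier>\n",
              r$nucleotide_id, 3L * nchar(r$sequence) + 3L),
      "        </GBFeature_quals>\n",
      "      </GBFeature>\n",
      "    </GBSeq_feature-table>\n",
      sprintf("    <GBSeq_sequence>%s</GBSeq_sequence>\n", seq_lower),
      "  </GBSeq>\n"
    )
  }
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<GBSet>\n",
    paste(vapply(records, entry, character(1)), collapse = ""),
    "</GBSet>\n"
  )
}

orders_csv_text <- function(records) {
  rows <- vapply(records, function(r) {
    sprintf("%s,\"%s\"", r$name$raw, paste(r$affected_orders, collapse = ", "))
  }, character(1))
  paste(c("protein,orders", rows), collapse = "\n")
}

#' Write a complete offline fixture set
#'
#' Emits `nomenclature.html`, `entrez.xml` and `orders.csv` into
#' `out_dir`. Every 5th nomenclature row carries no NCBI hyperlink (and
#' consequently no Entrez entry), so the raw vs processed count split is
#' exercised. Output is byte-identical for identical `seed`/`n`.
#'
#' @param out_dir Output directory (created if missing).
#' @param n Number of synthetic proteins.
#' @param seed Integer seed.
#' @return Named character vector of the three written paths.
#' @export
generate_fixture_files <- function(out_dir, n = 6L, seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  records <- fixture_records(n, seed = seed)
  linkless <- seq_len(n) %% 5L == 0L
  paths <- c(
    nomenclature = file.path(out_dir, "nomenclature.html"),
    entrez = file.path(out_dir, "entrez.xml"),
    orders = file.path(out_dir, "orders.csv")
  )
  writeLines(nomenclature_html_text(records, linkless), paths[["nomenclature"]],
             useBytes = TRUE)
  writeLines(entrez_xml_text(records[!linkless]), paths[["entrez"]],
             useBytes = TRUE)
  writeLines(orders_csv_text(records), paths[["orders"]], useBytes = TRUE)
  paths
}
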