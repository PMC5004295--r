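EFETCH_BASE_URL <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"

#' Parse the Bt toxin nomenclature HTML table
#'
#' The Bt toxin nomenclature site publishes the full toxin list as an HTML
#' table. This reads that document (or any fixture emulating it), takes the
#' first table whose header row mentions the protein-name column, and
#' returns one entry per protein row. Only rows carrying an NCBI protein
#' hyperlink yield a GI number; the others are kept in `raw_count` but not
#' in the entry list.
#'
#' @param document HTML text, or a path to an HTML file.
#' @return A list with `entries` — a [tibble::tibble()] with columns
#'   `name`, `ncbi_gi`, `source_row_index`, one row per linked protein —
#'   and `raw_count`, the number of protein rows found.
#' @export
parse_nomenclature_html <- function(document) {
  if (!is_string(document)) {
    cry_abort("document must be HTML text or a file path", "crykit_argument_error")
  }
  html <- if (!grepl("[<\n]", document) && file.exists(document)) {
    xml2::read_html(document)
  } else {
    xml2::read_html(document)
  }
  tables <- xml2::xml_find_all(html, ".//table")
  if (length(tables) == 0L) {
    cry_abort("no <table> found in the nomenclature document",
              "crykit_structure_error")
  }
  table <- NULL
  for (t in tables) {
    header <- xml2::xml_find_first(t, ".//tr")
    if (!inherits(header, "xml_missing") &&
        grepl("protein|name", tolower(xml2::xml_text(header)))) {
      table <- t
      break
    }
  }
  if (is.null(table)) table <- tables[[1]]

  rows <- xml2::xml_find_all(table, ".//tr")
  # drop the header row: the first row containing <th> cells (or the first row)
  has_th <- vapply(rows, function(r) {
    length(xml2::xml_find_all(r, "./th")) > 0L
  }, logical(1))
  data_rows <- if (any(has_th)) rows[!has_th] else rows[-1]

  names <- character(); gis <- character(); idx <- integer()
  raw_count <- 0L
  for (i in seq_along(data_rows)) {
    row <- data_rows[[i]]
    cells <- xml2::xml_find_all(row, "./td")
    if (length(cells) == 0L) next
    name <- trimws(xml2::xml_text(cells[[1]]))
    if (!nzchar(name)) {
      cry_warn(sprintf("nomenclature row %d has no protein name; skipped", i))
      next
    }
    raw_count <- raw_count + 1L
    hrefs <- xml2::xml_attr(xml2::xml_find_all(row, ".//a"), "href")
    hrefs <- hrefs[!is.na(hrefs) & grepl("ncbi", hrefs, ignore.case = TRUE)]
    gi <- NA_character_
    for (h in hrefs) {
      digits <- regmatches(h, regexpr("[0-9]+", h))
      if (length(digits) == 1L && nzchar(digits)) { gi <- digits; break }
    }
    if (!is.na(gi)) {
      names <- c(names, name); gis <- c(gis, gi); idx <- c(idx, i)
    }
  }
  list(
    entries = tibble::tibble(name = names, ncbi_gi = gis,
                             source_row_index = idx),
    raw_count = raw_count
  )
}

#' Build Entrez efetch requests for a set of protein GI numbers
#'
#' Renders the NCBI efetch call used to retrieve protein records:
#' `db=protein`, `retmode=xml`, the GI numbers comma-joined, plus the
#' `tool` and `email` identification parameters NCBI etiquette requires.
#' Long id lists are split into chunks.
#'
#' @param gis Character vector of GI numbers (non-empty).
#' @param config A [crykit_config()]; supplies `entrez_tool`,
#'   `entrez_email` and `chunk_size`.
#' @return List of `efetch_request` objects, each with `base_url`, `tool`,
#'   `email`, `db`, `retmode` and `ids`. Concatenating the `ids` of all
#'   requests reproduces `gis` exactly.
#' @export
build_efetch_requests <- function(gis, config = crykit_config()) {
  if (length(gis) == 0L) {
    cry_abort("gis must contain at least one GI number", "crykit_argument_error")
  }
  if (is.null(config$entrez_email) || !nzchar(config$entrez_email %||% "")) {
    cry_abort(
      "config$entrez_email is required: the Entrez service asks every client to identify a contact e-mail",
      "crykit_config_error"
    )
  }
  chunk_size <- config$chunk_size %||% 200L
  chunks <- split(as.character(gis),
                  ceiling(seq_along(gis) / chunk_size))
  lapply(unname(chunks), function(ids) {
    structure(
      list(base_url = EFETCH_BASE_URL, tool = config$entrez_tool,
           email = config$entrez_email, db = "protein", retmode = "xml",
           ids = ids),
      class = "efetch_request"
    )
  })
}

#' Render an efetch request as a URL
#'
#' @param request An `efetch_request` from [build_efetch_requests()].
#' @return The full query URL string.
#' @export
efetch_url <- function(request) {
  stopifnot(inherits(request, "efetch_request"))
  paste0(
    request$base_url, "?",
    "tool=", utils::URLencode(request$tool, reserved = TRUE),
    "&email=", utils::URLencode(request$email, reserved = TRUE),
    "&db=", request$db,
    "&retmode=", request$retmode,
    "&id=", paste(request$ids, collapse = ",")
  )
}

#' Fetch efetch requests from the live Entrez service
#'
#' Performs the HTTP requests with NCBI-polite pacing (>= 0.34 s between
#' calls) and up to 3 retries per request with exponential backoff.
#' Requires network access; all parsing works equally on pre-fetched
#' documents, so tests and offline runs never call this.
#'
#' @param requests List of `efetch_request` objects.
#' @param pause Seconds to sleep between requests.
#' @param retries Retries per request.
#' @return Character vector of XML documents, one per request.
#' @export
fetch_efetch_xml <- function(requests, pause = 0.34, retries = 3L) {
  vapply(seq_along(requests), function(i) {
    if (i > 1L) Sys.sleep(pause)
    url <- efetch_url(requests[[i]])
    delay <- 0.5
    for (attempt in seq_len(retries + 1L)) {
      doc <- tryCatch({
        con <- url(url, open = "rb")
        on.exit(close(con), add = TRUE)
        paste(readLines(con, warn = FALSE), collapse = "\n")
      }, error = function(e) e)
      if (!inherits(doc, "error")) return(doc)
      if (attempt <= retries) { Sys.sleep(delay); delay <- delay * 2 }
    }
    cry_abort(
      sprintf("Entrez efetch failed after %d attempts: %s", retries + 1L,
              conditionMessage(doc)),
      "crykit_network_error"
    )
  }, character(1))
}

# region label must read "Domain 1/2/3" or "domain I/II/III" (any case)
DOMAIN_LABEL_RE <- "^\\s*domain\\s*(1|2|3|I{1,3})\\s*$"

domain_label_index <- function(label) {
  m <- regmatches(label, regexec(DOMAIN_LABEL_RE, label, ignore.case = TRUE))[[1]]
  if (length(m) == 0L) return(NA_integer_)
  switch(toupper(m[2]), "1" = 1L, "2" = 2L, "3" = 3L,
         "I" = 1L, "II" = 2L, "III" = 3L, NA_integer_)
}

#' Parse Entrez efetch protein XML (GBSet dialect)
#'
#' Reads the XML the protein efetch endpoint returns (`GBSet` of `GBSeq`
#' entries) into plain records: GI, accession, definition, the amino acid
#' sequence, any region features labelled "Domain 1/2/3" (or I/II/III),
#' the literature references, and the id of the encoding nucleotide record
#' (taken from the CDS `coded_by` qualifier). Entries without a sequence
#' are dropped with a warning.
#'
#' @param document XML text or a path to an XML file.
#' @return List of `entrez_protein_record` objects.
#' @export
parse_entrez_xml <- function(document) {
  if (!is_string(document)) {
    cry_abort("document must be XML text or a file path", "crykit_argument_error")
  }
  xml <- tryCatch(
    xml2::read_xml(document),
    error = function(e) cry_abort(
      sprintf("malformed Entrez XML: %s", conditionMessage(e)),
      "crykit_parse_error"
    )
  )
  entries <- xml2::xml_find_all(xml, ".//GBSeq")
  records <- list()
  for (entry in entries) {
    text1 <- function(xpath) {
      node <- xml2::xml_find_first(entry, xpath)
      if (inherits(node, "xml_missing")) NA_character_ else xml2::xml_text(node)
    }
    accession <- text1("./GBSeq_primary-accession")
    sequence <- text1("./GBSeq_sequence")
    if (is.na(sequence) || !nzchar(sequence)) {
      cry_warn(sprintf("Entrez entry %s has no sequence; dropped",
                       accession %||% "?"))
      next
    }
    seqids <- xml2::xml_text(
      xml2::xml_find_all(entry, "./GBSeq_other-seqids/GBSeqid"))
    gi <- sub("^gi\\|", "", grep("^gi\\|", seqids, value = TRUE))
    gi <- if (length(gi) >= 1L) gi[[1]] else NA_character_

    feats <- xml2::xml_find_all(entry, "./GBSeq_feature-table/GBFeature")
    regions <- list()
    nucleotide_id <- NA_character_
    for (f in feats) {
      key <- xml2::xml_text(xml2::xml_find_first(f, "./GBFeature_key"))
      quals <- xml2::xml_find_all(f, "./GBFeature_quals/GBQualifier")
      qnames <- vapply(quals, function(q)
        xml2::xml_text(xml2::xml_find_first(q, "./GBQualifier_name")), character(1))
      qvals <- vapply(quals, function(q)
        xml2::xml_text(xml2::xml_find_first(q, "./GBQualifier_value")), character(1))
      if (identical(key, "CDS")) {
        coded_by <- qvals[qnames == "coded_by"]
        if (length(coded_by) == 1L) {
          nucleotide_id <- sub(":.*$", "", sub("^complement\\(", "", coded_by))
        }
      }
      if (identical(key, "Region")) {
        label <- qvals[qnames == "region_name"]
        label <- if (length(label) >= 1L) label[[1]] else ""
        from <- xml2::xml_text(xml2::xml_find_first(
          f, "./GBFeature_intervals/GBInterval/GBInterval_from"))
        to <- xml2::xml_text(xml2::xml_find_first(
          f, "./GBFeature_intervals/GBInterval/GBInterval_to"))
        if (!is.na(from) && !is.na(to)) {
          regions <- c(regions, list(list(label = label,
                                          start = as.integer(from),
                                          end = as.integer(to))))
        }
      }
    }
    refs <- lapply(
      xml2::xml_find_all(entry, "./GBSeq_references/GBReference"),
      function(r) {
        list(
          title = xml2::xml_text(xml2::xml_find_first(r, "./GBReference_title")),
          authors = paste(xml2::xml_text(xml2::xml_find_all(
            r, "./GBReference_authors/GBAuthor")), collapse = ", "),
          citation = xml2::xml_text(xml2::xml_find_first(r, "./GBReference_journal"))
        )
      })
    protein_id <- text1("./GBSeq_accession-version")
    if (is.na(protein_id)) protein_id <- accession
    records <- c(records, list(structure(
      list(
        gi = gi,
        accession = accession,
        protein_id = protein_id,
        definition = text1("./GBSeq_definition"),
        sequence = toupper(sequence),
        region_features = regions,
        references = refs,
        linked_nucleotide_id = nucleotide_id
      ),
      class = "entrez_protein_record"
    )))
  }
  records
}

#' Assemble a data package from nomenclature entries and Entrez records
#'
#' Matches nomenclature entries to Entrez protein records by GI number and
#' builds one [protein_record()] per match. Region features labelled as
#' domains provide the domain regions (first three, ordered by start);
#' affected insect orders are joined in by protein name from the orders
#' table. Unmatched entries are logged as warnings, never errors.
#'
#' @param entries Tibble of nomenclature entries
#'   (see [parse_nomenclature_html()]).
#' @param raw_count Number of rows in the nomenclature table.
#' @param entrez List of records from [parse_entrez_xml()].
#' @param orders_table Optional orders table from [read_orders_table()].
#' @return A [data_package()].
#' @export
assemble_records <- function(entries, raw_count, entrez,
                             orders_table = NULL) {
  by_gi <- setNames(entrez, vapply(entrez, `[[`, character(1), "gi"))
  records <- list()
  for (i in seq_len(nrow(entries))) {
    name <- entries$name[i]
    gi <- entries$ncbi_gi[i]
    er <- by_gi[[gi]]
    if (is.null(er)) {
      cry_warn(sprintf("no Entrez record for %s (gi %s); entry skipped", name, gi))
      next
    }
    cname <- tryCatch(parse_cry_name(name), crykit_parse_error = function(e) {
      cry_warn(sprintf("unparseable protein name '%s'; entry skipped", name))
      NULL
    })
    if (is.null(cname)) next

    regs <- er$region_features
    dom_idx <- vapply(regs, function(r) domain_label_index(r$label), integer(1))
    regs <- regs[!is.na(dom_idx)]
    if (length(regs) > 0L) {
      regs <- regs[order(vapply(regs, `[[`, integer(1), "start"))]
      regs <- utils::head(regs, 3L)
      # keep the labelled numbering when it is a valid increasing 1-3 set,
      # otherwise renumber sequentially by position
      lab_idx <- vapply(regs, function(r) domain_label_index(r$label), integer(1))
      if (anyDuplicated(lab_idx) > 0L || is.unsorted(lab_idx, strictly = TRUE)) {
        lab_idx <- seq_along(regs)
      }
      domains <- lapply(seq_along(regs), function(k) {
        domain_region(lab_idx[k], regs[[k]]$start, regs[[k]]$end)
      })
    } else {
      domains <- list()
    }

    orders <- character()
    if (!is.null(orders_table)) {
      hit <- tolower(orders_table$protein) == tolower(name)
      if (any(hit)) orders <- orders_table$orders[[which(hit)[1]]]
    }
    records <- c(records, list(protein_record(
      name = cname, gi = er$gi, accession = er$accession,
      protein_id = er$protein_id %||% er$accession,
      nucleotide_id = er$linked_nucleotide_id,
      sequence = er$sequence, domains = domains,
      affected_orders = orders, references = er$references
    )))
  }
  data_package(records = records, raw_count = raw_count)
}

#' Read a protein-to-affected-orders table
#'
#' The orders table maps each protein name to the insect orders it is
#' toxic to. The normative format is CSV/TSV with columns `protein` and
#' `orders` (orders comma-separated within the cell).
#'
#' @param path CSV or TSV file (delimiter inferred from the extension;
#'   `.tsv`/`.tab` read as tab-separated).
#' @return A tibble with columns `protein` (character) and `orders`
#'   (list of character vectors).
#' @export
read_orders_table <- function(path) {
  if (!file.exists(path)) {
    cry_abort(sprintf("orders table not found: %s", path), "crykit_io_error")
  }
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("protein", "orders") %in% names(df))) {
    cry_abort("orders table must have 'protein' and 'orders' columns",
              "crykit_structure_error")
  }
  tibble::tibble(
    protein = as.character(df$protein),
    orders = lapply(strsplit(as.character(df$orders), ","), trimws)
  )
}
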