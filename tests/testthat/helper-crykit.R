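# Shared fixtures and independent oracles for the test suite.

# Brute-force global alignment score by exhaustive recursion: the optimum
# over all alignments of a and b under substitution matrix S and linear
# gap penalty g. Independent of the DP implementation under test; only
# usable at tiny lengths.
bf_align_score <- function(a, b, S, g) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L) return(-g * nb)
  if (nb == 0L) return(-g * na)
  a1 <- substr(a, 1, 1); b1 <- substr(b, 1, 1)
  ra <- substr(a, 2, na); rb <- substr(b, 2, nb)
  max(
    bf_align_score(ra, rb, S, g) + S[a1, b1],
    bf_align_score(ra, b, S, g) - g,
    bf_align_score(a, rb, S, g) - g
  )
}

# all sequences of the given length over an alphabet
enumerate_seqs <- function(length, alphabet) {
  if (length == 0L) return("")
  grid <- do.call(expand.grid, rep(list(alphabet), length))
  apply(grid, 1, paste, collapse = "")
}

# a tiny hand-written nomenclature table: 3 protein rows, 2 with NCBI
# protein hyperlinks, one with a plain accession
nomenclature_html_3rows <- function() {
  paste(
    "<html><body>",
    "<table>",
    "<tr><th>Protein Name</th><th>Link</th></tr>",
    "<tr><td>Cry1Aa1</td><td><a href='https://www.ncbi.nlm.nih.gov/protein/142037'>AAA22353</a></td></tr>",
    "<tr><td>Cry1Ab1</td><td>AAA22330 (no link)</td></tr>",
    "<tr><td>Cry2Aa1</td><td><a href='https://www.ncbi.nlm.nih.gov/protein/142065'>AAA22335</a></td></tr>",
    "</table>",
    "</body></html>",
    sep = "\n"
  )
}

# minimal GBSet document: one entry, 50-residue sequence, one Domain 1
# region feature at 5..20
entrez_xml_one_entry <- function(sequence = paste(rep("ACDEFGHIKL", 5), collapse = "")) {
  sprintf(paste(
    "<?xml version='1.0'?>",
    "<GBSet><GBSeq>",
    "<GBSeq_primary-accession>AAA22353</GBSeq_primary-accession>",
    "<GBSeq_accession-version>AAA22353.1</GBSeq_accession-version>",
    "<GBSeq_definition>insecticidal crystal protein</GBSeq_definition>",
    "<GBSeq_other-seqids><GBSeqid>gi|142037</GBSeqid></GBSeq_other-seqids>",
    "<GBSeq_references><GBReference>",
    "<GBReference_title>A title</GBReference_title>",
    "<GBReference_authors><GBAuthor>Doe,J.</GBAuthor></GBReference_authors>",
    "<GBReference_journal>J. Test 1:1</GBReference_journal>",
    "</GBReference></GBSeq_references>",
    "<GBSeq_feature-table><GBFeature>",
    "<GBFeature_key>Region</GBFeature_key>",
    "<GBFeature_location>5..20</GBFeature_location>",
    "<GBFeature_intervals><GBInterval>",
    "<GBInterval_from>5</GBInterval_from><GBInterval_to>20</GBInterval_to>",
    "</GBInterval></GBFeature_intervals>",
    "<GBFeature_quals><GBQualifier>",
    "<GBQualifier_name>region_name</GBQualifier_name>",
    "<GBQualifier_value>Domain 1</GBQualifier_value>",
    "</GBQualifier></GBFeature_quals>",
    "</GBFeature>",
    "<GBFeature><GBFeature_key>CDS</GBFeature_key><GBFeature_quals>",
    "<GBQualifier><GBQualifier_name>coded_by</GBQualifier_name>",
    "<GBQualifier_value>M11250.1:1..153</GBQualifier_value></GBQualifier>",
    "</GBFeature_quals></GBFeature>",
    "</GBSeq_feature-table>",
    "<GBSeq_sequence>%s</GBSeq_sequence>",
    "</GBSeq></GBSet>",
    sep = "\n"
  ), tolower(sequence))
}

# a small record with a fixed sequence and chosen domains
make_record <- function(name = "Cry1Aa1", sequence = strrep("ACDEFGHIKL", 10),
                        domains = list(domain_region(1, 5, 30),
                                       domain_region(2, 41, 70),
                                       domain_region(3, 75, 95))) {
  protein_record(
    name = name, gi = "1", accession = "TEST00001",
    protein_id = "TEST00001.1", nucleotide_id = "TESTNT1.1",
    sequence = sequence, domains = domains,
    affected_orders = c("Lepidoptera")
  )
}

table1_catalog <- function() {
  load_model_catalog(system.file("extdata", "structural_models.csv",
                                 package = "crykit"))
}
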