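---
title: "Cry protein retrieval and pairwise conservation analysis with crykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cry protein retrieval and pairwise conservation analysis with crykit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crykit)
```

## Scope and model

`crykit` automates a comparison workflow for *Bacillus thuringiensis*
crystal (Cry) toxins: gather the protein records behind the Bt toxin
nomenclature table, store them in a versioned extraction file, select a
region (the complete sequence or one of the three structural domains),
align it, and quantify how conserved the two proteins are column by
column. The package takes no position on *why* two toxins differ in order
specificity; it produces the difference list and statistics a researcher
starts from.

The conservation model is the Clustal consensus-symbol convention. Two
aligned residues are

* **conserved** (C) when identical (and standard — the ambiguity letters
  B, Z, X and the rare U belong to no physicochemical group, so even an
  identical pair of them is scored non-conserved, a deliberately
  conservative choice);
* a **conserved mutation** (CM) when different but members of one strong
  group (STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW);
* a **semi-conserved mutation** (SCM) when they share only a weak group
  (CSA, ATV, SAG, STNK, STPA, SGND, SDEQK, NDEQHK, NEQHRK, FVLIM, HFY);
* **non-conserved** (NC) otherwise, including every column where one row
  carries a gap.

Strong membership is tested before weak, so an S/A pair (in strong STA
*and* weak CSA) is a conserved mutation. These are exactly the groups
behind the `:` and `.` symbols that Clustal-family aligners print, which
is why conservation is always *recomputed* from the rows — consensus
lines in Clustal files are discarded on read.

Columns where **both** rows carry gaps can occur when the pair is taken
out of a larger multiple alignment; they are excluded before
classification. This keeps the partition invariant exact:
`C + CM + SCM + NC` equals the number of classified columns, for every
alignment. A column with exactly one gap counts as NC — the residual
class — rather than being dropped, so insertions and deletions show up in
the totals.

### Percentages

Each statistic is reported twice, once per protein: `100 * count /
length_i`, where `length_i` is the ungapped residue count of the region
protein *i* contributed to the alignment. Rounding is **half up** to two
decimals, implemented in integer arithmetic (`(10000*count) %/% length`
plus a remainder test) so results never depend on binary floating-point
representation. Half-up is the only mode consistent with the worked
report values the package reproduces (52/202 → 25.74 and 52/205 → 25.37;
the latter is 25.3658…, which truncation would print as 25.36).

### Coordinates

Alignment columns are numbered from 1. A difference record maps each
residue back to its 1-based ungapped sequence position (the count of
non-gap characters up to that column) and reports the neighbouring
positions, reproducing the `^205^H^207^` presentation: the residue at
position 206 flanked by 205 and 207. Positions are absent (`NA`) on the
gap side of an indel column and at sequence termini. The difference
*location* is the alignment column, which for near-identical pairs
coincides closely with the sequence position; the two coincide exactly in
gapless alignments.

## Retrieval and the extraction file

The extraction stage mirrors the public data flow: parse the nomenclature
HTML table (first table whose header mentions the protein-name column;
one entry per row, keeping only rows with an NCBI protein hyperlink — the
GI number is the digit run in the link target); build `efetch` requests
against `https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi` with
`db=protein`, `retmode=xml`, comma-joined ids, and the `tool`/`email`
identification NCBI asks of clients (live mode refuses to run without an
e-mail, paces requests at ≥ 0.34 s and retries 3 times with exponential
backoff); parse the returned GBSet XML (sequence, region features,
references, the `coded_by` qualifier for the nucleotide id); and assemble
one record per GI match. Region features labelled `Domain 1/2/3` (or
I/II/III, any case) become domain regions — at most three, ordered by
start, keeping the labelled numbering when it is consistent. Ids are
chunked 200 per request; chunking provably preserves order and
multiplicity.

Every parser also accepts pre-fetched documents, so the whole pipeline
runs offline; the fixture generator (below) provides the documents.

The extraction file is a single self-describing UTF-8 JSON document with
a mandatory `schema_version`. JSON was chosen over the original
tool-specific XML pair because one schema with explicit versioning makes
the round-trip property (`load(save(pkg))` identical to `pkg`) trivial to
state and test; unknown versions are a distinct, versioned load error.
Coordinates are 1-based inclusive throughout, matching NCBI region
features.

## Alignment

Three external aligners of record (Clustal Omega, ClustalW, MUSCLE) plus
MAFFT are driven through adapters: sequences go out as FASTA with
sanitized ids (a reversible map — external tools mangle spaces), aligned
FASTA is requested back from every tool so one parser is canonical, and
tool output is surfaced in the log. Clustal-format files are supported
read-only.

The built-in aligner is a plain Needleman–Wunsch global alignment with a
linear gap penalty — a dependency-free pairwise path so analysis never
requires a binary. Defaults are BLOSUM62 (as shipped with Biostrings) and
gap 8, standard protein settings. Traceback ties resolve deterministically
diagonal > up > left, so identical inputs give identical alignments. The
implementation is validated two independent ways: exhaustive recursive
enumeration of all alignments at short lengths (exhaustive over all
sequence pairs of lengths ≤ 2 on a 4-letter alphabet, sampled across all
length combinations up to 6 — full enumeration of all length-≤6 pairs is
combinatorially out of reach, ~15 M pairs), and score agreement with
`Biostrings::pairwiseAlignment` under the same linear-gap model at
realistic lengths. The built-in path is pairwise only; three or more
sequences require an external tool.

## The fixture generator

The generator emulates the *structure* of the retrieval inputs, not their
biology: Cry-named records (valid four-rank names), random sequences of
realistic three-domain size (about 570–750 residues: a 40–80 residue
leader, Domain 1 of 200–240, Domain 2 of 180–220, Domain 3 of 130–160
with short linkers), nomenclature HTML where every 5th row lacks an NCBI
hyperlink (so raw vs processed counts differ), matching GBSet XML, and an
orders table. Sequences are uniform random over the 20 standard residues —
they have no real composition bias, no homology, and no conserved cores,
so fixture alignments are far more divergent than real Cry pairs. Passing
tests therefore demonstrate the *bookkeeping* (partition, coordinates,
round-trips, determinism under a seed, byte-identical regeneration), not
biological plausibility of the statistics. Controlled-substitution pairs
(`fixture_pair()`) give closed-form expectations: K substitutions in a
gapless pair yield exactly K differences and `length − K` conserved
columns.

Two checks intentionally depend on the outside world and are documented
as integration-grade: reproducing a specific published difference
(Cry1Ab1 H vs Cry1Aa1 Y at location 206) needs the live Entrez service,
and exact conserved counts on real protein pairs depend on the aligner
version used. Test problem sizes (500 random 50-column alignments, 120
oracle pairs, 4–6 record pipelines) were chosen as comfortably
demonstrative for the properties at stake.

## Degenerate inputs and edge policies

* Records with fewer than three annotated domains: FASTA generation
  writes 1 + d files (complete plus each available domain) with a
  warning, rather than failing or padding.
* An empty wanted-order set means *no filter* — all records retained;
  matching is case-insensitive.
* Malformed nomenclature rows are skipped with a logged warning; Entrez
  entries without a sequence are dropped with a warning; a document
  without a table, or truncated XML, is a hard error.
* Validation (`validate_record()`) never throws: it returns a list of
  violations naming field and rule, and saving an invalid package is
  refused.
* `classify_column("-", "-")` is an argument error by contract; the
  analysis layer removes such columns first.
* Model ids classify purely by shape (4 characters → PDB, 9 → PMDB);
  anything else is an error naming the id. One catalog row may cover two
  proteins (a binary-complex model), which is why deposited model ids and
  proteins with models are counted independently.

## Limitations

* No protein structure prediction and no parsing of PDB/PMDB coordinate
  files — the catalog stores ids and URLs only.
* The built-in aligner has no affine gap model; for sensitive alignments
  of distant pairs use an external tool.
* Difference records are descriptive; the package draws no conclusions
  about receptor binding or specificity from them.
* The bundled structural-model registry is a point-in-time transcription
  (including its original spellings); deposition counts change as new
  models are published.
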