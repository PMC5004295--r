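test_that("identical sequences align gaplessly with the diagonal score", {
  sc <- builtin_scoring()
  seq <- "HDACYWKLMN"
  aln <- align_builtin(seq, seq, sc)
  expect_equal(aln$rows[1], seq)
  expect_equal(aln$rows[2], seq)
  chars <- strsplit(seq, "")[[1]]
  expect_equal(aln$parameters$score,
               sum(sc$matrix[cbind(chars, chars)]))
})

test_that("the ACD/AD example attains the enumerated optimum", {
  # identity scoring (match 1, mismatch 0, gap 1): best score over all
  # alignments of ACD vs AD is 2 matches - 1 gap = 1
  sc <- identity_scoring(match = 1, mismatch = 0, gap = 1)
  aln <- align_builtin("ACD", "AD", sc)
  expect_equal(aln$parameters$score, 1)
  expect_equal(nchar(aln$rows[1]), 3)
  expect_equal(sum(strsplit(aln$rows[2], "")[[1]] == "-"), 1)
  expect_equal(aln$parameters$score,
               bf_align_score("ACD", "AD", sc$matrix, sc$gap))
})

test_that("alignment score is symmetric for random pairs", {
  set.seed(81)
  sc <- builtin_scoring()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    a <- paste(sample(aa, 8, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 8, replace = TRUE), collapse = "")
    expect_equal(align_builtin(a, b, sc)$parameters$score,
                 align_builtin(b, a, sc)$parameters$score)
  }
})

test_that("builtin scores equal the brute-force recursion (exhaustive <=2)", {
  sc <- builtin_scoring()
  seqs <- c(enumerate_seqs(1, c("A", "C", "D", "E")),
            enumerate_seqs(2, c("A", "C", "D", "E")))
  for (a in seqs) {
    for (b in seqs) {
      expect_equal(align_builtin(a, b, sc)$parameters$score,
                   bf_align_score(a, b, sc$matrix, sc$gap),
                   info = paste(a, "vs", b))
    }
  }
})

test_that("builtin scores equal the brute-force recursion (sampled to length 6)", {
  set.seed(4242)
  sc <- builtin_scoring()
  alphabet <- c("A", "C", "D", "E")
  for (rep in 1:60) {
    a <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(align_builtin(a, b, sc)$parameters$score,
                 bf_align_score(a, b, sc$matrix, sc$gap),
                 info = paste(a, "vs", b))
  }
})

test_that("builtin scores match an independent aligner implementation", {
  # Biostrings' pairwiseAlignment with zero opening cost and extension 8 is
  # the same linear-gap global model; it serves as a second, independent
  # oracle at realistic lengths
  set.seed(7)
  sc <- builtin_scoring()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    a <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 35, replace = TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 0, gapExtension = 8
    )
    expect_equal(align_builtin(a, b, sc)$parameters$score,
                 Biostrings::score(ref))
  }
})

test_that("ungapping the rows reproduces the input sequences", {
  set.seed(12)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    a <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    aln <- align_builtin(a, b)
    expect_equal(gsub("-", "", aln$rows[1]), a)
    expect_equal(gsub("-", "", aln$rows[2]), b)
    expect_equal(nchar(aln$rows[1]), nchar(aln$rows[2]))
  }
})

test_that("degenerate alignment inputs are rejected", {
  expect_error(align_builtin("", "ACD"), class = "crykit_argument_error")
  expect_error(align_builtin("ACD", ""), class = "crykit_argument_error")
  expect_error(align_builtin("AC8", "ACD"), class = "crykit_argument_error")
})

test_that("run_msa validates its tool and sequence arguments", {
  seqs <- c(a = "ACDEF", b = "ACDFF")
  expect_error(run_msa("tcoffee", seqs), class = "crykit_argument_error")
  expect_error(run_msa("builtin", seqs[1]), class = "crykit_argument_error")
  expect_error(run_msa("builtin", c(a = "ACD", b = "ACD", c = "ACD")),
               class = "crykit_argument_error")
})

test_that("a missing external executable raises an environment error", {
  expect_error(
    run_msa("clustalo", c(a = "ACDEF", b = "ACDFF"),
            executable_path = file.path(tempdir(), "no-such-clustalo")),
    class = "crykit_environment_error"
  )
})

test_that("the external-tool adapter round-trips ids through a stub binary", {
  # a stand-in 'clustalo' that copies its already-aligned input to the
  # output file exercises the full adapter path (id sanitizing, output
  # parsing, id restoration, ungap-identity contract) without the binary
  skip_on_os("windows")
  stub <- withr::local_tempfile(fileext = ".sh")
  writeLines(c(
    "#!/bin/sh",
    "# minimal clustalo argument convention: -i <in> -o <out> ...",
    "in=\"\"; out=\"\"",
    "while [ $# -gt 0 ]; do",
    "  case $1 in",
    "    -i) in=$2; shift 2;;",
    "    -o) out=$2; shift 2;;",
    "    *) shift;;",
    "  esac",
    "done",
    "cp \"$in\" \"$out\"",
    "echo aligned >&2"
  ), stub)
  Sys.chmod(stub, "0755")
  seqs <- c("Cry1Aa1 D2" = "ACDEF", "Cry2Aa1 D2" = "ACDFF")
  res <- suppressMessages(run_msa("clustalo", seqs, executable_path = stub))
  expect_equal(res$ids, names(seqs))
  expect_equal(res$rows, unname(seqs))
  expect_equal(res$algorithm, "clustalo")
})

test_that("aligned FASTA and Clustal documents read back consistently", {
  fasta <- ">seqA\nAC-D\n>seqB\nACED\n"
  aln <- read_alignment(fasta, format = "fasta")
  expect_equal(aln$ids, c("seqA", "seqB"))
  expect_equal(aln$rows, c("AC-D", "ACED"))

  clustal <- paste(
    "CLUSTAL O(1.2.4) multiple sequence alignment",
    "",
    "seqA      AC-DEF",
    "seqB      ACEDEF",
    "          ** ***",
    sep = "\n"
  )
  aln2 <- read_alignment(clustal, format = "clustal")
  expect_equal(aln2$ids, c("seqA", "seqB"))
  expect_equal(aln2$rows, c("AC-DEF", "ACEDEF"))
})

test_that("multi-block Clustal documents concatenate per id", {
  clustal <- paste(
    "CLUSTAL W (1.83) multiple sequence alignment",
    "",
    "s1        ACDEF 5",
    "s2        ACDFF 5",
    "          *** *",
    "",
    "s1        GHIKL 10",
    "s2        GH-KL 9",
    "          ** **",
    sep = "\n"
  )
  aln <- read_alignment(clustal, format = "clustal")
  expect_equal(aln$rows, c("ACDEFGHIKL", "ACDFFGH-KL"))
})

test_that("ragged or empty alignment files are format errors", {
  expect_error(read_alignment(">a\nACDE\n>b\nACDEF\n", format = "fasta"),
               class = "crykit_format_error")
  expect_error(read_alignment("   \n", format = "fasta"),
               class = "crykit_format_error")
  expect_error(read_alignment("CLUSTAL\n\n", format = "clustal"),
               class = "crykit_format_error")
})

test_that("write_alignment/read_alignment round-trips ids and rows", {
  aln <- fixture_alignment(n_cols = 40, seed = 3)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  back <- read_alignment(path, format = "fasta")
  expect_identical(back$ids, aln$ids)
  expect_identical(back$rows, aln$rows)
})
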