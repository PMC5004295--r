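test_that("column classification follows the strong/weak group convention", {
  expect_equal(classify_column("A", "A")$value, "CONSERVED")
  # H and Y share the strong group HY: a conserved mutation
  expect_equal(classify_column("H", "Y")$value, "CONSERVED_MUTATION")
  # S and A share strong STA even though weak CSA also contains both:
  # strong membership is checked first
  expect_equal(classify_column("S", "A")$value, "CONSERVED_MUTATION")
  # C and S share only the weak group CSA
  expect_equal(classify_column("C", "S")$value, "SEMI_CONSERVED_MUTATION")
  # E and F share no group
  expect_equal(classify_column("E", "F")$value, "NON_CONSERVED")

  gap <- classify_column("A", "-")
  expect_equal(gap$value, "NON_CONSERVED")
  expect_true(gap$gap_involved)

  # identical nonstandard letters belong to no group
  expect_equal(classify_column("X", "X")$value, "NON_CONSERVED")
})

test_that("classification rejects invalid characters and all-gap columns", {
  expect_error(classify_column("A", "8"), class = "crykit_argument_error")
  expect_error(classify_column("-", "-"), class = "crykit_argument_error")
})

test_that("classification is symmetric over all character pairs", {
  chars <- c(strsplit("ACDEFGHIKLMNPQRSTVWYBZXU", "")[[1]], "-")
  for (a in chars) {
    for (b in chars) {
      if (a == "-" && b == "-") next
      expect_identical(classify_column(a, b)$value,
                       classify_column(b, a)$value)
    }
  }
})

test_that("alignment columns map to ungapped sequence positions", {
  expect_equal(column_to_seq_position("--AB-C", 3), 1L)
  expect_equal(column_to_seq_position("--AB-C", 6), 3L)
  expect_true(is.na(column_to_seq_position("--AB-C", 5)))
  expect_error(column_to_seq_position("--AB-C", 7),
               class = "crykit_argument_error")
  expect_error(column_to_seq_position("--AB-C", 0),
               class = "crykit_argument_error")
})

test_that("a self-alignment has no differences and c equals the length", {
  aln <- alignment_result(c("p1", "p2"), c("ACDEF", "ACDEF"))
  res <- analyze_pair(aln, 1, 2)
  expect_equal(nrow(res$differences), 0)
  expect_equal(res$stats$c, 5L)
  expect_equal(res$stats$cm + res$stats$scm + res$stats$nc, 0L)
  pct <- res$stats$percentages
  expect_equal(pct$pct_1[pct$statistic == "C"], 100)
})

test_that("a single substitution is located, classified and positioned", {
  aln <- alignment_result(c("p1", "p2"), c("ACDEF", "ACDFF"))
  res <- analyze_pair(aln, 1, 2)
  expect_equal(nrow(res$differences), 1)
  d <- res$differences
  expect_equal(d$location, 4L)
  expect_equal(d$residue_1, "E")
  expect_equal(d$residue_2, "F")
  expect_equal(d$position_1, 4L)
  expect_equal(d$position_2, 4L)
  expect_equal(d$classification, "NON_CONSERVED")
  expect_equal(d$flank_before_1, 3L)
  expect_equal(d$flank_after_1, 5L)
  expect_equal(res$stats$c, 4L)
  expect_equal(res$stats$nc, 1L)
})

test_that("strong-group substitutions still appear in the differences list", {
  aln <- alignment_result(c("Cry1Ab1", "Cry1Aa1"), c("AHC", "AYC"))
  res <- analyze_pair(aln, 1, 2)
  expect_equal(nrow(res$differences), 1)
  expect_equal(res$differences$classification, "CONSERVED_MUTATION")
  expect_equal(res$differences$residue_1, "H")
  expect_equal(res$differences$residue_2, "Y")
})

test_that("all-gap columns are excluded before pairwise analysis", {
  # rows 1 and 2 share a column where both are gaps (possible when a third
  # sequence was in the original alignment)
  aln <- alignment_result(c("p1", "p2", "p3"),
                          c("AC-DE", "AC-DF", "ACXDE"))
  res <- analyze_pair(aln, 1, 2)
  expect_equal(res$stats$c + res$stats$cm + res$stats$scm + res$stats$nc, 4L)
  expect_equal(res$differences$location, 5L)  # original column coordinates
})

test_that("gap columns count as non-conserved with positions absent", {
  aln <- alignment_result(c("p1", "p2"), c("ACDEF", "AC-EF"))
  res <- analyze_pair(aln, 1, 2)
  expect_equal(res$stats$nc, 1L)
  d <- res$differences
  expect_equal(d$residue_2, "-")
  expect_true(is.na(d$position_2))
  expect_equal(d$position_1, 3L)
  expect_true(d$gap_involved)
})

test_that("percentages follow the exact half-up two-decimal rule", {
  expect_identical(compute_percentage(52, 202), 25.74)
  expect_identical(compute_percentage(52, 205), 25.37)
  expect_identical(compute_percentage(0, 100), 0)
  expect_identical(compute_percentage(100, 100), 100)
  # exact .xx5 halves round up, not to even
  expect_identical(compute_percentage(1, 4000), 0.03)
  expect_identical(compute_percentage(3, 4000), 0.08)
  expect_error(compute_percentage(5, 0), class = "crykit_argument_error")
})

test_that("statistics counts partition the classified columns (property)", {
  for (seed in 1:25) {
    aln <- fixture_alignment(n_cols = 60, gap_rate = 0.15, seed = seed)
    res <- analyze_pair(aln, 1, 2)
    r1 <- strsplit(aln$rows[1], "")[[1]]
    r2 <- strsplit(aln$rows[2], "")[[1]]
    classified <- sum(!(r1 == "-" & r2 == "-"))
    s <- res$stats
    expect_equal(s$c + s$cm + s$scm + s$nc, classified)
    expect_equal(s$c_plus_cm, s$c + s$cm)
  }
})

test_that("swapping the pair swaps residue columns but preserves counts", {
  aln <- fixture_alignment(n_cols = 80, gap_rate = 0.1, seed = 99)
  ab <- analyze_pair(aln, 1, 2)
  ba <- analyze_pair(aln, 2, 1)
  expect_equal(ab$stats$c, ba$stats$c)
  expect_equal(ab$stats$cm, ba$stats$cm)
  expect_equal(ab$stats$scm, ba$stats$scm)
  expect_equal(ab$stats$nc, ba$stats$nc)
  expect_equal(ab$stats$length_1, ba$stats$length_2)
  expect_equal(ab$differences$residue_1, ba$differences$residue_2)
  expect_equal(ab$differences$position_1, ba$differences$position_2)
  expect_equal(ab$differences$location, ba$differences$location)
})

test_that("difference coordinates read back the original residues (property)", {
  for (seed in c(7, 77)) {
    aln <- fixture_alignment(n_cols = 70, gap_rate = 0.2, seed = seed)
    res <- analyze_pair(aln, 1, 2)
    seq1 <- gsub("-", "", aln$rows[1])
    seq2 <- gsub("-", "", aln$rows[2])
    d <- res$differences
    for (k in seq_len(nrow(d))) {
      if (!is.na(d$position_1[k])) {
        expect_equal(substr(seq1, d$position_1[k], d$position_1[k]),
                     d$residue_1[k])
      }
      if (!is.na(d$position_2[k])) {
        expect_equal(substr(seq2, d$position_2[k], d$position_2[k]),
                     d$residue_2[k])
      }
    }
  }
})

test_that("each added substitution increases disagreement monotonically", {
  base <- fixture_pair(length = 120, n_substitutions = 0, seed = 31)$seq_a
  prev_disagree <- -1L
  chars <- strsplit(base, "")[[1]]
  set.seed(31)
  positions <- sample.int(120, 15)
  variant <- chars
  for (k in seq_along(positions)) {
    p <- positions[k]
    variant[p] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 chars[p]), 1)
    aln <- alignment_result(c("a", "b"),
                            c(base, paste(variant, collapse = "")))
    s <- analyze_pair(aln, 1, 2)$stats
    disagree <- s$cm + s$scm + s$nc
    expect_gt(disagree, prev_disagree)
    prev_disagree <- disagree
  }
})

test_that("controlled fixture pairs have closed-form statistics", {
  fp <- fixture_pair(length = 150, n_substitutions = 12, seed = 8)
  aln <- alignment_result(c("a", "b"), c(fp$seq_a, fp$seq_b))
  res <- analyze_pair(aln, 1, 2)
  expect_equal(nrow(res$differences), 12)
  expect_equal(res$differences$location, fp$positions)
  expect_equal(res$stats$c, 150L - 12L)
})

test_that("analyze_pair validates its indices", {
  aln <- alignment_result(c("a", "b"), c("ACD", "ACD"))
  expect_error(analyze_pair(aln, 1, 1), class = "crykit_argument_error")
  expect_error(analyze_pair(aln, 1, 3), class = "crykit_argument_error")
  expect_error(analyze_pair(aln, "a", "nope"), class = "crykit_argument_error")
})
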