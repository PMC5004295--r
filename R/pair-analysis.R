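#' Percentage of a count over a region length, rounded half up
#'
#' Report percentages are `100 * count / length` rounded *half up* to two
#' decimals (2575/100 not banker's rounding), computed in exact integer
#' arithmetic so the printed value never depends on floating-point
#' representation.
#'
#' @param count Non-negative count of alignment columns.
#' @param length Positive number of residues of the reference region.
#' @return The percentage, a numeric with two-decimal resolution.
#' @examples
#' compute_percentage(52, 202)  # 25.74
#' compute_percentage(52, 205)  # 25.37 (25.3658... rounds up)
#' @export
compute_percentage <- function(count, length) {
  if (length(length) != 1L || is.na(length) || length <= 0) {
    cry_abort("length must be a positive number", "crykit_argument_error")
  }
  if (length(count) != 1L || is.na(count) || count < 0) {
    cry_abort("count must be non-negative", "crykit_argument_error")
  }
  if (count == round(count) && length == round(length)) {
    p <- 10000 * count
    base <- p %/% length
    if (2 * (p %% length) >= length) base <- base + 1
    base / 100
  } else {
    floor(10000 * count / length + 0.5) / 100
  }
}

#' Build the conservation statistics block of a pairwise analysis
#'
#' Holds the column counts — C (conserved), CM (conserved mutations),
#' SCM (semi-conserved mutations), NC (non-conserved) and the derived
#' C+CM — together with the two aligned regions' residue counts and the
#' per-protein percentages (each count divided by that protein's region
#' length, per [compute_percentage()]).
#'
#' @param c,cm,scm,nc Column counts; their sum is the number of classified
#'   alignment columns.
#' @param length_1,length_2 Ungapped residue counts of the two aligned
#'   regions.
#' @return An `analysis_statistics` object with a `percentages` tibble
#'   (columns `statistic`, `count`, `pct_1`, `pct_2`).
#' @export
analysis_statistics <- function(c, cm, scm, nc, length_1, length_2) {
  counts <- c(C = c, CM = cm, SCM = scm, `C+CM` = c + cm, NC = nc)
  if (any(counts < 0)) {
    cry_abort("statistic counts must be non-negative", "crykit_argument_error")
  }
  pct <- tibble::tibble(
    statistic = names(counts),
    count = as.integer(unname(counts)),
    pct_1 = unname(vapply(counts, compute_percentage, numeric(1),
                          length = length_1)),
    pct_2 = unname(vapply(counts, compute_percentage, numeric(1),
                          length = length_2))
  )
  structure(
    list(c = as.integer(c), cm = as.integer(cm), scm = as.integer(scm),
         nc = as.integer(nc), c_plus_cm = as.integer(c + cm),
         length_1 = as.integer(length_1), length_2 = as.integer(length_2),
         percentages = pct),
    class = "analysis_statistics"
  )
}

#' @export
print.analysis_statistics <- function(x, ...) {
  cat(sprintf("<analysis_statistics> %d classified columns (regions: %d / %d residues)\n",
              x$c + x$cm + x$scm + x$nc, x$length_1, x$length_2))
  print(as.data.frame(x$percentages), row.names = FALSE)
  invisible(x)
}

#' Analyze the differences between two rows of an alignment
#'
#' The core pairwise analysis: takes two rows of an alignment, drops the
#' columns where both carry gaps (they only arise when more sequences were
#' aligned together), classifies every remaining column
#' ([classify_column()]), collects every non-identical column into a
#' difference record, and tallies the C/CM/SCM/C+CM/NC statistics with
#' per-protein percentages. Each difference carries the alignment column
#' (`location`), both characters, their ungapped sequence positions (`NA`
#' at a gap) and the flanking positions, reproducing the field notation
#' `^205^H^207^` (residue at position 206, flanked by 205 and 207).
#'
#' @param alignment An [alignment_result()].
#' @param idx_1,idx_2 Distinct row indices or sequence ids.
#' @return A `pair_analysis` list: `ids`, `differences` (a tibble with one
#'   row per differing column, ascending by `location`), and `stats`
#'   (an [analysis_statistics()]).
#' @export
analyze_pair <- function(alignment, idx_1 = 1L, idx_2 = 2L) {
  stopifnot(inherits(alignment, "alignment_result"))
  resolve <- function(idx) {
    if (is.character(idx)) {
      pos <- match(idx, alignment$ids)
      if (is.na(pos)) cry_abort(sprintf("no sequence '%s' in the alignment", idx),
                                "crykit_argument_error")
      return(pos)
    }
    idx <- as.integer(idx)
    if (is.na(idx) || idx < 1L || idx > length(alignment$ids)) {
      cry_abort(sprintf("row index %s out of range 1..%d", idx,
                        length(alignment$ids)),
                "crykit_argument_error")
    }
    idx
  }
  i1 <- resolve(idx_1); i2 <- resolve(idx_2)
  if (i1 == i2) {
    cry_abort("idx_1 and idx_2 must name different rows", "crykit_argument_error")
  }
  r1 <- strsplit(alignment$rows[i1], "")[[1]]
  r2 <- strsplit(alignment$rows[i2], "")[[1]]

  keep <- !(r1 == "-" & r2 == "-")
  cols <- which(keep)
  a <- r1[keep]; b <- r2[keep]

  pos1_all <- cumsum(r1 != "-"); pos2_all <- cumsum(r2 != "-")
  len1 <- pos1_all[length(pos1_all)]; len2 <- pos2_all[length(pos2_all)]

  classes <- classify_columns(a, b)
  counts <- table(factor(classes, levels = COLUMN_CLASSES))
  stats <- analysis_statistics(
    c = counts[["CONSERVED"]], cm = counts[["CONSERVED_MUTATION"]],
    scm = counts[["SEMI_CONSERVED_MUTATION"]], nc = counts[["NON_CONSERVED"]],
    length_1 = len1, length_2 = len2
  )

  diff_idx <- which(a != b)
  pos_or_na <- function(chars, pos_all, sel) {
    ifelse(chars[sel] == "-", NA_integer_, pos_all[cols[sel]])
  }
  p1 <- pos_or_na(a, pos1_all, diff_idx)
  p2 <- pos_or_na(b, pos2_all, diff_idx)
  flank <- function(pos, len, off) {
    out <- pos + off
    out[is.na(pos) | out < 1L | out > len] <- NA_integer_
    out
  }
  differences <- tibble::tibble(
    location = cols[diff_idx],
    residue_1 = a[diff_idx], residue_2 = b[diff_idx],
    position_1 = p1, position_2 = p2,
    flank_before_1 = flank(p1, len1, -1L), flank_after_1 = flank(p1, len1, 1L),
    flank_before_2 = flank(p2, len2, -1L), flank_after_2 = flank(p2, len2, 1L),
    classification = classes[diff_idx],
    gap_involved = a[diff_idx] == "-" | b[diff_idx] == "-"
  )
  structure(
    list(ids = alignment$ids[c(i1, i2)], differences = differences,
         stats = stats, alignment = alignment, indices = c(i1, i2)),
    class = "pair_analysis"
  )
}

#' @export
print.pair_analysis <- function(x, ...) {
  cat(sprintf("<pair_analysis> %s vs %s: %d difference(s)\n",
              x$ids[1], x$ids[2], nrow(x$differences)))
  print(x$stats)
  invisible(x)
}
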