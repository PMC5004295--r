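#' Default scoring scheme for the built-in aligner
#'
#' BLOSUM62 with a linear gap penalty of 8 per gap character — standard
#' protein defaults for a global aligner without affine gaps.
#'
#' @param matrix Square substitution matrix with residue dimnames;
#'   defaults to BLOSUM62 as shipped with Biostrings.
#' @param gap Positive linear gap penalty per gap character.
#' @return A list with `matrix` and `gap`.
#' @export
builtin_scoring <- function(matrix = NULL, gap = 8) {
  if (is.null(matrix)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    matrix <- env$BLOSUM62
  }
  if (gap <= 0) {
    cry_abort("gap penalty must be positive (it is subtracted)",
              "crykit_argument_error")
  }
  list(matrix = matrix, gap = as.numeric(gap))
}

#' Identity scoring scheme (match/mismatch/gap)
#'
#' Convenience scheme for tests and didactic examples.
#'
#' @param match,mismatch Scores for equal/unequal residues.
#' @param gap Positive linear gap penalty.
#' @return A scoring list as for [builtin_scoring()].
#' @export
identity_scoring <- function(match = 1, mismatch = 0, gap = 1) {
  letters <- EXTENDED_AA
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  list(matrix = m, gap = as.numeric(gap))
}

#' Globally align two sequences (built-in Needleman-Wunsch)
#'
#' Dependency-free pairwise global alignment with a linear gap penalty:
#' the score of an alignment is the sum of substitution-matrix entries for
#' aligned residue pairs minus `gap` per gap character, and the returned
#' alignment attains the optimum. Traceback is deterministic, resolving
#' ties in the order diagonal > up (gap in the second sequence) > left
#' (gap in the first).
#'
#' @param seq_a,seq_b Non-empty amino acid strings.
#' @param scoring A scoring list, see [builtin_scoring()].
#' @param id_a,id_b Identifiers for the two rows.
#' @return An [alignment_result()] with `algorithm = "builtin-nw"` and the
#'   optimal `score` in its `parameters`.
#' @examples
#' aln <- align_builtin("HDACY", "HEACY")
#' aln$parameters$score
#' @export
align_builtin <- function(seq_a, seq_b, scoring = builtin_scoring(),
                          id_a = "seq_1", id_b = "seq_2") {
  if (!is_string(seq_a) || !nzchar(seq_a) || !is_string(seq_b) || !nzchar(seq_b)) {
    cry_abort("both sequences must be non-empty strings", "crykit_argument_error")
  }
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  for (s in c(a = seq_a, b = seq_b)) {
    bad <- unique(valid_sequence_letters(s))
    if (length(bad) > 0L) {
      cry_abort(sprintf("invalid residue letter(s): %s",
                        paste0("'", bad, "'", collapse = ", ")),
                "crykit_argument_error")
    }
  }
  S <- scoring$matrix; g <- scoring$gap
  a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
  missing <- setdiff(unique(c(a, b)), rownames(S))
  if (length(missing) > 0L) {
    cry_abort(sprintf("substitution matrix lacks letter(s): %s",
                      paste(missing, collapse = ", ")),
              "crykit_argument_error")
  }
  n <- length(a); m <- length(b)
  ai <- match(a, rownames(S)); bi <- match(b, colnames(S))

  # H: (n+1) x (m+1) score matrix; P: traceback (1 diag, 2 up, 3 left)
  H <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)
  H[1, ] <- -g * (0:m); H[, 1] <- -g * (0:n)
  P[1, -1] <- 3L; P[-1, 1] <- 2L
  for (i in seq_len(n)) {
    srow <- S[ai[i], bi]
    prev <- H[i, ]
    cur <- numeric(m + 1L)
    ptr <- integer(m + 1L)
    cur[1] <- -g * i
    for (j in seq_len(m)) {
      d <- prev[j] + srow[j]
      u <- prev[j + 1L] - g
      l <- cur[j] - g
      # tie order: diagonal > up > left
      if (d >= u && d >= l) { cur[j + 1L] <- d; ptr[j + 1L] <- 1L }
      else if (u >= l) { cur[j + 1L] <- u; ptr[j + 1L] <- 2L }
      else { cur[j + 1L] <- l; ptr[j + 1L] <- 3L }
    }
    H[i + 1L, ] <- cur
    P[i + 1L, ] <- c(0L, ptr[-1])
  }
  P[-1, 1] <- 2L

  # traceback
  row_a <- character(); row_b <- character()
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    move <- P[i, j]
    if (move == 1L) {
      row_a <- c(a[i - 1L], row_a); row_b <- c(b[j - 1L], row_b)
      i <- i - 1L; j <- j - 1L
    } else if (move == 2L) {
      row_a <- c(a[i - 1L], row_a); row_b <- c("-", row_b)
      i <- i - 1L
    } else {
      row_a <- c("-", row_a); row_b <- c(b[j - 1L], row_b)
      j <- j - 1L
    }
  }
  alignment_result(
    ids = c(id_a, id_b),
    rows = c(paste(row_a, collapse = ""), paste(row_b, collapse = "")),
    algorithm = "builtin-nw",
    parameters = list(score = H[n + 1L, m + 1L], gap = g)
  )
}
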