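MSA_TOOLS <- c("clustalo", "clustalw", "muscle", "mafft")

find_executable <- function(tool, executable_path = NULL, config = NULL) {
  cand <- executable_path %||% config$executables[[tool]] %||% Sys.which(tool)
  if (!nzchar(cand) || (!file.exists(cand) && !nzchar(Sys.which(cand)))) {
    cry_abort(
      sprintf(paste0(
        "external aligner '%s' not found. Install it and put it on PATH ",
        "(e.g. via conda/apt: clustalo, clustalw, muscle, mafft) or pass ",
        "executable_path; for a dependency-free pairwise alignment use ",
        "align_builtin()."), tool),
      "crykit_environment_error"
    )
  }
  cand
}

#' Run an external multiple sequence aligner
#'
#' Thin adapters over the Clustal Omega, ClustalW, MUSCLE and MAFFT
#' command-line tools: the sequences are written to a temporary FASTA file
#' (ids sanitized for tool safety, with a reversible map), the tool is
#' invoked requesting aligned-FASTA output, its stdout/stderr are surfaced
#' via `message()`, and the output is parsed back. Use
#' `tool = "builtin"` with exactly two sequences for the dependency-free
#' pairwise path ([align_builtin()]).
#'
#' @param tool `"clustalo"`, `"clustalw"`, `"muscle"`, `"mafft"` or
#'   `"builtin"`.
#' @param sequences Named character vector (or list) of >= 2 sequences.
#' @param params Extra command-line arguments passed through verbatim.
#' @param executable_path Explicit path to the tool binary.
#' @param selector Optional [region_selector()] recorded in the result.
#' @param config Optional [crykit_config()] consulted for executables.
#' @return An [alignment_result()] whose ungapped rows equal the input
#'   sequences.
#' @export
run_msa <- function(tool, sequences, params = character(),
                    executable_path = NULL, selector = NULL, config = NULL) {
  if (!is_string(tool) || !tool %in% c(MSA_TOOLS, "builtin")) {
    cry_abort(
      sprintf("unknown alignment tool '%s' (available: %s, builtin)",
              tool, paste(MSA_TOOLS, collapse = ", ")),
      "crykit_argument_error"
    )
  }
  sequences <- unlist(sequences)
  if (length(sequences) < 2L) {
    cry_abort("alignment needs at least 2 sequences", "crykit_argument_error")
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    cry_abort("sequences must be named", "crykit_argument_error")
  }

  if (tool == "builtin") {
    if (length(sequences) != 2L) {
      cry_abort(
        "the builtin aligner is pairwise only; use an external tool for >= 3 sequences",
        "crykit_argument_error"
      )
    }
    res <- align_builtin(sequences[[1]], sequences[[2]],
                         id_a = names(sequences)[1], id_b = names(sequences)[2])
    res$selector <- selector
    return(res)
  }

  exe <- find_executable(tool, executable_path, config)

  # sanitized, reversible id map: external tools mangle spaces and pipes
  safe_ids <- sprintf("s%04d", seq_along(sequences))
  id_map <- setNames(names(sequences), safe_ids)

  infile <- tempfile(fileext = ".fasta")
  outfile <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  write_fasta(setNames(toupper(as.character(sequences)), safe_ids), infile)

  spec <- switch(tool,
    clustalo = list(args = c("-i", infile, "-o", outfile, "--outfmt=fa",
                             "--force"), stdout = TRUE),
    clustalw = list(args = c(paste0("-INFILE=", infile),
                             paste0("-OUTFILE=", outfile),
                             "-OUTPUT=FASTA", "-ALIGN"), stdout = TRUE),
    muscle = list(args = c("-align", infile, "-output", outfile),
                  stdout = TRUE),
    mafft = list(args = c("--auto", infile), stdout = outfile)
  )
  args <- c(spec$args, params)
  out <- suppressWarnings(system2(
    exe, args,
    stdout = if (isTRUE(spec$stdout)) TRUE else spec$stdout,
    stderr = TRUE
  ))
  status <- attr(out, "status") %||% 0L
  captured <- if (is.character(out)) paste(out, collapse = "\n") else ""
  if (nzchar(captured)) {
    message(sprintf("[%s] %s", tool, captured))
  }
  if (status != 0L || !file.exists(outfile)) {
    cry_abort(
      sprintf("%s exited with status %s:\n%s", tool, status, captured),
      "crykit_tool_error"
    )
  }
  aln <- read_alignment(outfile, format = "fasta")
  # restore original ids (tools may append descriptions after whitespace)
  restored <- id_map[sub("\\s.*$", "", aln$ids)]
  if (anyNA(restored)) {
    cry_abort(sprintf("%s output ids do not match the submitted sequences", tool),
              "crykit_tool_error")
  }
  result <- alignment_result(
    ids = unname(restored), rows = aln$rows, algorithm = tool,
    parameters = list(args = paste(args, collapse = " ")),
    selector = selector
  )
  # contract check: ungapped rows must reproduce the inputs
  for (i in seq_along(result$ids)) {
    if (!identical(ungap(result$rows[i]),
                   toupper(sequences[[result$ids[i]]]))) {
      cry_abort(
        sprintf("%s output for '%s' does not reproduce the input sequence",
                tool, result$ids[i]),
        "crykit_tool_error"
      )
    }
  }
  result
}
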