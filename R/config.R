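#' Runtime configuration
#'
#' Collects the knobs shared across the pipeline: Entrez client
#' identification, request chunking, paths to external aligner
#' executables, the offline-fixtures flag and the fixture-generator seed.
#' Live retrieval refuses to run without a contact e-mail.
#'
#' @param entrez_tool Client name sent to the Entrez service.
#' @param entrez_email Contact e-mail sent to the Entrez service; required
#'   for live retrieval, unused offline.
#' @param chunk_size GI numbers per efetch request (default 200).
#' @param executables Named list mapping aligner tool names to executable
#'   paths, overriding `PATH` lookup.
#' @param fixtures Logical; operate on local fixture files only.
#' @param seed Integer seed for the fixture generator.
#' @return A `crykit_config` list.
#' @export
crykit_config <- function(entrez_tool = "crykit", entrez_email = NULL,
                          chunk_size = 200L, executables = list(),
                          fixtures = FALSE, seed = NULL) {
  structure(
    list(entrez_tool = entrez_tool, entrez_email = entrez_email,
         chunk_size = as.integer(chunk_size), executables = executables,
         fixtures = isTRUE(fixtures),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "crykit_config"
  )
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Recognised keys match the arguments of [crykit_config()]; command-line
#' flags override file values.
#'
#' @param path Path to the configuration file.
#' @param base A [crykit_config()] supplying defaults.
#' @return A `crykit_config`.
#' @export
read_config <- function(path, base = crykit_config()) {
  if (!file.exists(path)) {
    cry_abort(sprintf("config file not found: %s", path), "crykit_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- base
  for (line in lines) {
    kv <- regmatches(line, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) == 0L) next
    key <- kv[2]; value <- trimws(kv[3])
    switch(key,
      entrez_tool = { out$entrez_tool <- value },
      entrez_email = { out$entrez_email <- value },
      chunk_size = { out$chunk_size <- as.integer(value) },
      fixtures = { out$fixtures <- tolower(value) %in% c("true", "1", "yes") },
      seed = { out$seed <- as.integer(value) },
      NULL
    )
  }
  out
}
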