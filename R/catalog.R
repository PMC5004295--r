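# Structural-model catalog: which Cry proteins have deposited 3D models,
# in PDB (4-character ids) or PMDB (9-character ids starting "PM"), and
# which are described in the literature without a deposited model.

MODEL_SOURCES <- c("PDB", "PMDB", "UNAVAILABLE")

#' Classify a structural model id by its repository
#'
#' Deposited Cry models live in two repositories distinguished purely by
#' id shape: 4-character ids are PDB entries, 9-character ids (starting
#' `"PM"`) are PMDB entries.
#'
#' @param model_id Non-empty model id string.
#' @return `"PDB"` or `"PMDB"`.
#' @examples
#' classify_model_id("1CIY")       # PDB
#' classify_model_id("PM0074964")  # PMDB
#' @export
classify_model_id <- function(model_id) {
  if (!is_string(model_id) || !nzchar(model_id)) {
    cry_abort("model_id must be a non-empty string", "crykit_argument_error")
  }
  n <- nchar(model_id)
  if (n == 4L) return("PDB")
  if (n == 9L) return("PMDB")
  cry_abort(
    sprintf("cannot classify model id '%s': %d characters (PDB ids have 4, PMDB ids 9)",
            model_id, n),
    "crykit_classification_error"
  )
}

#' Construct a structural-model catalog entry
#'
#' @param protein_names One or more Cry protein names covered by the entry
#'   (a binary-complex model may cover two proteins).
#' @param model_id Model id, or `NA` when no model is deposited.
#' @param source `"PDB"`, `"PMDB"` or `"UNAVAILABLE"`; inferred from the
#'   id when omitted.
#' @param note Free-text caveat (e.g. "Binary protein complex").
#' @param reference Free-text reference status.
#' @return A `structural_model` object.
#' @export
structural_model <- function(protein_names, model_id = NA_character_,
                             source = NULL, note = "", reference = "") {
  if (length(protein_names) < 1L) {
    cry_abort("a structural model entry needs at least one protein name",
              "crykit_argument_error")
  }
  has_id <- !is.na(model_id) && nzchar(model_id)
  if (is.null(source)) {
    source <- if (has_id) classify_model_id(model_id) else "UNAVAILABLE"
  }
  source <- match.arg(source, MODEL_SOURCES)
  if ((source == "UNAVAILABLE") == has_id) {
    cry_abort("source is UNAVAILABLE if and only if model_id is absent",
              "crykit_argument_error")
  }
  if (has_id && classify_model_id(model_id) != source) {
    cry_abort(sprintf("model id '%s' does not look like a %s id",
                      model_id, source),
              "crykit_classification_error")
  }
  structure(
    list(protein_names = as.character(protein_names),
         model_id = if (has_id) model_id else NA_character_,
         source = source, note = note, reference = reference),
    class = "structural_model"
  )
}

#' Load a structural-model catalog from CSV/TSV
#'
#' Expected columns: `proteins` (`;`-separated when an entry covers more
#' than one protein), `model_id` (empty when undeposited), `source`,
#' `note`, `reference`. The package bundles a transcription of the
#' published registry of deposited Cry models under
#' `system.file("extdata", "structural_models.csv", package = "crykit")`,
#' which is the default.
#'
#' @param path Catalog file.
#' @return List of [structural_model()] entries.
#' @export
load_model_catalog <- function(path = system.file("extdata", "structural_models.csv",
                                                  package = "crykit")) {
  if (!file.exists(path)) {
    cry_abort(sprintf("catalog file not found: %s", path), "crykit_io_error")
  }
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    id <- df$model_id[i]
    structural_model(
      protein_names = trimws(strsplit(df$proteins[i], ";")[[1]]),
      model_id = if (is.na(id) || !nzchar(id)) NA_character_ else id,
      source = df$source[i],
      note = df$note[i] %||% "",
      reference = df$reference[i] %||% ""
    )
  })
}

#' Summarize a structural-model catalog
#'
#' @param catalog List of [structural_model()] entries.
#' @return A list with `deposited_models` (distinct deposited model ids),
#'   `proteins_with_models` (distinct proteins attached to at least one
#'   deposited id) and `undeposited_proteins` (distinct proteins appearing
#'   only in entries without a model).
#' @export
catalog_summary <- function(catalog) {
  deposited <- Filter(function(m) m$source != "UNAVAILABLE", catalog)
  undeposited <- Filter(function(m) m$source == "UNAVAILABLE", catalog)
  ids <- unique(vapply(deposited, `[[`, character(1), "model_id"))
  with_models <- unique(unlist(lapply(deposited, `[[`, "protein_names")))
  only_undep <- setdiff(
    unique(unlist(lapply(undeposited, `[[`, "protein_names"))),
    with_models
  )
  list(
    deposited_models = length(ids),
    proteins_with_models = length(with_models),
    undeposited_proteins = length(only_undep)
  )
}

#' Build the download/entry URL for a deposited model
#'
#' URL patterns are configuration, not hard-coded truth: pass different
#' patterns if the repositories move. `%s` is replaced by the model id.
#'
#' @param model A [structural_model()] with a deposited id.
#' @param pdb_pattern,pmdb_pattern `sprintf` patterns for each repository.
#' @return URL string.
#' @export
model_url <- function(model,
                      pdb_pattern = "https://files.rcsb.org/download/%s.pdb",
                      pmdb_pattern = "https://bioinformatics.cineca.it/PMDB/user/search.php?idsearch=%s") {
  stopifnot(inherits(model, "structural_model"))
  if (model$source == "UNAVAILABLE") {
    cry_abort(
      sprintf("no deposited model for %s",
              paste(model$protein_names, collapse = "/")),
      "crykit_argument_error"
    )
  }
  sprintf(if (model$source == "PDB") pdb_pattern else pmdb_pattern,
          model$model_id)
}
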