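#' Read and write score tables
#'
#' Tabular IO for the engine. Supported formats: `csv`, `tsv` (both UTF-8,
#' header row, empty string = missing) and `parquet`. The format is
#' inferred from the file extension unless given explicitly.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"`, or `"parquet"`; `NULL` to infer from
#'   the extension.
#' @param id_cols Identifier columns that must be present in the table.
#' @return A tibble.
#' @export
read_score_table <- function(path, format = NULL,
                             id_cols = c("participant_id", "session_id")) {
  format <- format %||% infer_format(path)
  if (!file.exists(path)) {
    cs_abort(sprintf("File not found: %s.", path), kind = "io")
  }
  data <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE, na = "", progress = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE, na = "", progress = FALSE),
    parquet = tibble::as_tibble(arrow::read_parquet(path)),
    cs_abort(sprintf("Unsupported format '%s'.", format), kind = "io")
  )
  absent <- setdiff(id_cols, names(data))
  if (length(absent) > 0) {
    cs_abort(
      sprintf(
        "Identifier column(s) absent from %s: %s.",
        path, paste(absent, collapse = ", ")
      ),
      kind = "missing-column"
    )
  }
  data
}

#' @rdname read_score_table
#' @param data Data frame to write.
#' @export
write_score_table <- function(data, path, format = NULL) {
  format <- format %||% infer_format(path)
  switch(format,
    csv = readr::write_csv(data, path, na = "", progress = FALSE),
    tsv = readr::write_tsv(data, path, na = "", progress = FALSE),
    parquet = arrow::write_parquet(data, path),
    cs_abort(sprintf("Unsupported format '%s'.", format), kind = "io")
  )
  invisible(path)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv",
    tsv = "tsv",
    parquet = "parquet",
    cs_abort(
      sprintf(
        "Cannot infer a tabular format from '%s'; use csv, tsv, or parquet.",
        path
      ),
      kind = "io"
    )
  )
}

#' Read a score catalog from YAML
#'
#' The catalog document has four top-level keys: `missing_codes`,
#' `id_columns`, `scores` (a list of score definitions: `name`, `items`,
#' `kernel`, and kernel parameters such as `max_na`, `target_levels`,
#' `conditions`, `norms` — a file path relative to the catalog — and
#' `stratum_cols`), and `groups`. The document is schema-checked on load,
#' every definition is run through [validate_definition()], and
#' catalog-level invariants are checked with [validate_catalog()]; any
#' violation is an error whose message carries the document path of the
#' offending field.
#'
#' @param path Path to a YAML catalog.
#' @return A validated [catalog()].
#' @examples
#' read_catalog(system.file("extdata", "catalog.yaml",
#'   package = "cohortscores"
#' ))
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) {
    cs_abort(sprintf("Catalog file not found: %s.", path), kind = "io")
  }
  doc <- yaml::read_yaml(path)
  known <- c("missing_codes", "id_columns", "scores", "groups")
  unknown <- setdiff(names(doc), known)
  if (length(unknown) > 0) {
    cs_abort(
      sprintf(
        "Unknown top-level catalog key(s): %s.",
        paste(unknown, collapse = ", ")
      ),
      kind = "schema"
    )
  }
  if (!is.list(doc$scores) || length(doc$scores) == 0) {
    cs_abort("Catalog key `scores` must be a non-empty list.", kind = "schema")
  }
  definitions <- vector("list", length(doc$scores))
  for (i in seq_along(doc$scores)) {
    entry <- doc$scores[[i]]
    where <- sprintf("scores[%d]", i)
    for (required in c("name", "items", "kernel")) {
      if (is.null(entry[[required]])) {
        cs_abort(
          sprintf("%s.%s: required field is missing.", where, required),
          kind = "schema"
        )
      }
    }
    conditions <- NULL
    if (!is.null(entry$conditions)) {
      conditions <- lapply(entry$conditions, function(spec) {
        do.call(cond_spec, spec)
      })
    }
    norms <- NULL
    if (!is.null(entry$norms)) {
      norms_path <- file.path(dirname(path), entry$norms)
      norms <- read_norm_table(norms_path)
    }
    definitions[[i]] <- withCallingHandlers(
      score_definition(
        name = entry$name,
        items = unlist(entry$items),
        kernel = entry$kernel,
        max_na = entry$max_na,
        target_levels = if (!is.null(entry$target_levels)) {
          unlist(entry$target_levels)
        },
        conditions = conditions,
        norms = norms,
        stratum_cols = if (!is.null(entry$stratum_cols)) {
          unlist(entry$stratum_cols)
        },
        nm_companion = entry$nm_companion
      ),
      cohortscores_error = function(e) {
        cs_abort(
          sprintf("%s: %s", where, conditionMessage(e)),
          kind = "schema", parent = e
        )
      }
    )
    if (!is.null(entry$norms)) {
      attr(definitions[[i]], "norms_path") <- entry$norms
    }
  }
  cat_obj <- catalog(
    definitions = definitions,
    groups = doc$groups %||% list(),
    missing_codes = unlist(doc$missing_codes) %||% numeric(),
    id_columns = unlist(doc$id_columns) %||% c("participant_id", "session_id")
  )
  report <- validate_catalog(cat_obj)
  if (nrow(report) > 0) {
    cs_abort(
      c(
        sprintf("Catalog '%s' failed validation:", path),
        stats::setNames(
          paste0(report$field, ": ", report$message),
          rep("x", nrow(report))
        )
      ),
      kind = "schema"
    )
  }
  cat_obj
}

#' Write a score catalog to YAML
#'
#' Inverse of [read_catalog()]: re-reading the written file yields an
#' equal catalog.
#'
#' @param cat A [catalog()].
#' @param path Output path.
#' @export
write_catalog <- function(cat, path) {
  stopifnot(inherits(cat, "catalog"))
  scores <- lapply(cat$definitions, function(defn) {
    entry <- list(
      name = render_score_name(defn$name),
      items = as.list(defn$items),
      kernel = defn$kernel
    )
    if (!is.null(defn$max_na)) entry$max_na <- defn$max_na
    if (!is.null(defn$target_levels)) {
      entry$target_levels <- as.list(defn$target_levels)
    }
    if (!is.null(defn$conditions)) {
      entry$conditions <- lapply(defn$conditions, function(cond) {
        list(
          column = cond$column, comparator = cond$comparator,
          reference = if (length(cond$reference) > 1) {
            as.list(cond$reference)
          } else {
            cond$reference
          },
          missing_policy = cond$missing_policy
        )
      })
    }
    if (!is.null(attr(defn, "norms_path"))) {
      entry$norms <- attr(defn, "norms_path")
      if (!is.null(defn$stratum_cols)) {
        entry$stratum_cols <- as.list(defn$stratum_cols)
      }
    }
    entry$nm_companion <- defn$nm_companion
    entry
  })
  doc <- list(
    missing_codes = as.list(cat$missing_codes),
    id_columns = as.list(cat$id_columns),
    scores = unname(scores),
    groups = lapply(cat$groups, as.list)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Path to the exemplar catalog shipped with the package
#'
#' Covers the parent family-environment cohesion and conflict subscales
#' (`fc_p_fes`), the youth blood-pressure measure (`ph_y_bp`), and a
#' mental-health exemplar (`mh_p_ders` attunement subscale).
#'
#' @return A file path.
#' @export
example_catalog_path <- function() {
  system.file("extdata", "catalog.yaml", package = "cohortscores")
}
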