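#' Build a score catalog
#'
#' A catalog is the single source of truth the engine executes: a
#' collection of [score_definition()]s, named groups of scores that are
#' computed together (the `_all`-style convenience groups), the sentinel
#' codes that encode missingness in the raw items (e.g. numeric
#' refuse-to-answer / don't-know codes, recoded to missing before any
#' kernel runs), and the identifier columns of the tables it scores.
#'
#' @param definitions List of [score_definition()] objects.
#' @param groups Named list mapping a group identifier (a
#'   `domain_respondent_table` prefix such as `"ph_y_bp"`) to the ordered
#'   character vector of member score names.
#' @param missing_codes Item values treated as missing (default: none).
#' @param id_columns Identifier columns of the score tables (participant,
#'   event).
#'
#' @return A `catalog` object with fields `definitions` (named by rendered
#'   score name), `groups`, `missing_codes`, `id_columns`.
#' @examples
#' cat <- catalog(list(
#'   score_definition("ph_y_bp__sys_mean",
#'     items = sprintf("ph_y_bp__sys_%03d", 1:3), kernel = "ss_mean",
#'     max_na = 2
#'   )
#' ))
#' validate_catalog(cat)
#' @export
catalog <- function(definitions, groups = list(),
                    missing_codes = numeric(),
                    id_columns = c("participant_id", "session_id")) {
  if (!is.list(definitions) ||
    !all(vapply(definitions, inherits, logical(1), "score_definition"))) {
    cs_abort(
      "`definitions` must be a list of score_definition objects.",
      kind = "type"
    )
  }
  names(definitions) <- vapply(
    definitions, function(d) render_score_name(d$name), character(1)
  )
  groups <- lapply(groups, as.character)
  structure(
    list(
      definitions = definitions,
      groups = groups,
      missing_codes = missing_codes,
      id_columns = as.character(id_columns)
    ),
    class = "catalog"
  )
}

#' @export
print.catalog <- function(x, ...) {
  cat(
    "<catalog> ", length(x$definitions), " score(s), ",
    length(x$groups), " group(s)\n",
    sep = ""
  )
  cat("  id columns: ", paste(x$id_columns, collapse = ", "), "\n", sep = "")
  if (length(x$missing_codes) > 0) {
    cat(
      "  missing codes: ", paste(x$missing_codes, collapse = ", "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Validate a catalog
#'
#' Checks catalog-level invariants — unique score names, every group member
#' present among the definitions and sharing the group's
#' domain/respondent/table prefix — and rolls up [validate_definition()]
#' over every definition. Returns a report; an empty report means the
#' catalog is valid.
#'
#' @param cat A [catalog()].
#' @return A validation report tibble (`kind`, `field`, `message`).
#' @export
validate_catalog <- function(cat) {
  stopifnot(inherits(cat, "catalog"))
  report <- new_report()
  score_names <- names(cat$definitions)
  if (anyDuplicated(score_names) > 0) {
    dup <- unique(score_names[duplicated(score_names)])
    report <- report_add(
      report, "param", "scores",
      sprintf("duplicate score name(s): %s", paste(dup, collapse = ", "))
    )
  }
  for (i in seq_along(cat$definitions)) {
    defn_report <- validate_definition(cat$definitions[[i]])
    if (nrow(defn_report) > 0) {
      defn_report$field <- paste0(
        "scores[", i, "].", defn_report$field
      )
      report <- dplyr::bind_rows(report, defn_report)
      class(report) <- class(new_report())
    }
  }
  for (group in names(cat$groups)) {
    members <- cat$groups[[group]]
    absent <- setdiff(members, score_names)
    if (length(absent) > 0) {
      report <- report_add(
        report, "missing-score", paste0("groups.", group),
        sprintf(
          "member(s) not in definitions: %s", paste(absent, collapse = ", ")
        )
      )
    }
    prefixed <- startsWith(members, paste0(group, "_"))
    if (!all(prefixed)) {
      report <- report_add(
        report, "param", paste0("groups.", group),
        sprintf(
          "member(s) outside the group's prefix: %s",
          paste(members[!prefixed], collapse = ", ")
        )
      )
    }
  }
  report
}

#' List the scores or groups of a catalog
#'
#' @param cat A [catalog()].
#' @return `list_scores()`: character vector of score names;
#'   `list_groups()`: named list of member vectors.
#' @export
list_scores <- function(cat) {
  stopifnot(inherits(cat, "catalog"))
  names(cat$definitions)
}

#' @rdname list_scores
#' @export
list_groups <- function(cat) {
  stopifnot(inherits(cat, "catalog"))
  cat$groups
}
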