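#' Validate input data against a score definition
#'
#' The validate step of the validate-compute-return contract: checks that
#' every column the definition reads is present and of the type its kernel
#' requires. All violations are collected and reported at once (friendlier
#' for catalog-scale runs than failing on the first); [compute_score()]
#' raises exactly when this report is non-empty.
#'
#' @param data A data frame.
#' @param defn A [score_definition()].
#' @return A validation report tibble (`kind`, `field`, `message`).
#' @export
validate_input <- function(data, defn) {
  stopifnot(is.data.frame(data), inherits(defn, "score_definition"))
  report <- new_report()
  numeric_kernels <- c(
    "ss_mean", "ss_sum", "ss_prsum", "ss_max", "ss_mean_pos", "ss_tscore"
  )

  needed <- defn$items
  if (defn$kernel == "ss_count_cond") {
    needed <- union(
      needed,
      vapply(defn$conditions %||% list(), function(x) x$column, character(1))
    )
  }
  if (defn$kernel == "ss_tscore") {
    needed <- union(needed, defn$stratum_cols %||% character())
  }
  for (col in setdiff(needed, names(data))) {
    report <- report_add(
      report, "missing-column", col,
      sprintf("required column '%s' is absent from the data", col)
    )
  }
  if (defn$kernel %in% numeric_kernels) {
    present <- intersect(defn$items, names(data))
    for (col in present) {
      v <- data[[col]]
      if (!(is.numeric(v) || is.logical(v) || all(is.na(v)))) {
        report <- report_add(
          report, "type", col,
          sprintf(
            "column '%s' must be numeric for kernel %s (got %s)",
            col, defn$kernel, class(v)[[1]]
          )
        )
      }
    }
  }
  report
}

recode_missing <- function(m, missing_codes) {
  if (length(missing_codes) > 0) m[m %in% missing_codes] <- NA
  m
}

run_kernel <- function(data, defn, norms = NULL) {
  switch(defn$kernel,
    ss_count_cond = ss_count_cond(data, defn$conditions),
    ss_tscore = {
      norms <- norms %||% defn$norms
      stratum <- if (length(defn$stratum_cols %||% character()) > 0) {
        data[defn$stratum_cols]
      }
      ss_tscore(data[[defn$items]], norms, stratum)
    },
    ss_count = ss_count(data[defn$items], defn$target_levels),
    ss_nm = ss_nm(data[defn$items]),
    ss_mean_pos = ss_mean_pos(data[defn$items]),
    ss_mean = ss_mean(data[defn$items], defn$max_na),
    ss_sum = ss_sum(data[defn$items], defn$max_na),
    ss_prsum = ss_prsum(data[defn$items], defn$max_na),
    ss_max = ss_max(data[defn$items], defn$max_na)
  )
}

#' Compute one summary score
#'
#' Executes a [score_definition()] against a data frame following the
#' standard `data` / `name` / `combine` calling contract: validate the
#' inputs, run the scoring kernel row-wise, and return the score appended
#' to the input (default) or alongside the identifier columns only. If the
#' definition declares an `_nm` companion, the number-missing column is
#' computed alongside and emitted immediately after its parent score.
#'
#' @param data Data frame containing the definition's item columns (plus
#'   the identifier columns when `combine = FALSE`).
#' @param defn A [score_definition()].
#' @param name Output column name; defaults to the score's own name. When
#'   overridden, the `_nm` companion (if any) is named `<name>_nm`.
#' @param combine If `TRUE` (default), return the input data frame with
#'   the score column(s) appended; if `FALSE`, return only `id_cols` plus
#'   the score column(s).
#' @param max_na Optional override of the definition's missing-item
#'   tolerance.
#' @param missing_codes Sentinel item values recoded to missing before the
#'   kernel runs (e.g. numeric refuse-to-answer codes); usually supplied by
#'   the catalog.
#' @param norms Optional [norm_table()] overriding the definition's, for
#'   `ss_tscore` scores.
#' @param id_cols Identifier columns returned with `combine = FALSE`.
#' @param quiet If `FALSE`, log the number of rows scored and the number
#'   missing.
#'
#' @return A tibble; attribute `provenance` records, per emitted column,
#'   the definition and parameter values used and a content hash.
#'
#' @examples
#' d <- simulate_items(
#'   n_rows = 4, n_items = 9, levels = 0:1,
#'   pattern = missingness_pattern(per_row = c(0, 1, 2, 0), seed = 7),
#'   prefix = "fc_p_fes__cohes", seed = 7
#' )
#' defn <- score_definition("fc_p_fes__cohes_mean",
#'   items = sprintf("fc_p_fes__cohes_%03d", 1:9),
#'   kernel = "ss_mean", max_na = 1
#' )
#' compute_score(d, defn)
#' @export
compute_score <- function(data, defn, name = NULL, combine = TRUE,
                          max_na = NULL, missing_codes = NULL, norms = NULL,
                          id_cols = c("participant_id", "session_id"),
                          quiet = TRUE) {
  stopifnot(is.data.frame(data), inherits(defn, "score_definition"))
  if (!is.null(max_na)) {
    defn$max_na <- as.integer(max_na)
  }
  defn_report <- validate_definition(defn)
  if (nrow(defn_report) > 0) {
    cs_abort(
      c(
        sprintf(
          "Invalid definition for '%s':", render_score_name(defn$name)
        ),
        stats::setNames(defn_report$message, rep("x", nrow(defn_report)))
      ),
      kind = defn_report$kind[[1]]
    )
  }
  input_report <- validate_input(data, defn)
  if (nrow(input_report) > 0) {
    cs_abort(
      c(
        sprintf(
          "Invalid input for '%s':", render_score_name(defn$name)
        ),
        stats::setNames(input_report$message, rep("x", nrow(input_report)))
      ),
      kind = input_report$kind[[1]]
    )
  }

  work <- data
  if (length(missing_codes %||% numeric()) > 0) {
    for (col in intersect(defn$items, names(work))) {
      work[[col]] <- recode_missing(work[[col]], missing_codes)
    }
  }

  out_name <- name %||% default_score_name(defn)
  values <- run_kernel(work, defn, norms = norms)

  new_cols <- stats::setNames(list(values), out_name)
  if (defn$nm_companion && !defn$kernel %in% c("ss_nm", "ss_count_cond")) {
    nm_name <- if (is.null(name)) {
      render_score_name(score_name_sibling(defn$name, "nm"))
    } else {
      paste0(name, "_nm")
    }
    new_cols[[nm_name]] <- ss_nm(work[defn$items])
  }

  collisions <- intersect(names(new_cols), names(data))
  if (length(collisions) > 0) {
    cs_abort(
      sprintf(
        "Output column(s) already present in the data: %s.",
        paste(collisions, collapse = ", ")
      ),
      kind = "name-collision"
    )
  }

  if (!quiet) {
    rlang::inform(sprintf(
      "%s: scored %d row(s), %d missing.",
      out_name, nrow(data), sum(is.na(values))
    ))
  }

  params <- list(
    kernel = defn$kernel, items = defn$items, max_na = defn$max_na,
    target_levels = defn$target_levels, nm_companion = defn$nm_companion
  )
  provenance <- stats::setNames(
    rep(
      list(list(
        definition = render_score_name(defn$name),
        definition_hash = rlang::hash(defn),
        params = params
      )),
      length(new_cols)
    ),
    names(new_cols)
  )

  base <- if (combine) {
    tibble::as_tibble(data)
  } else {
    absent_ids <- setdiff(id_cols, names(data))
    if (length(absent_ids) > 0) {
      cs_abort(
        sprintf(
          "Identifier column(s) absent from data: %s.",
          paste(absent_ids, collapse = ", ")
        ),
        kind = "missing-column"
      )
    }
    tibble::as_tibble(data[id_cols])
  }
  out <- dplyr::bind_cols(base, tibble::as_tibble(new_cols))
  attr(out, "provenance") <- c(attr(data, "provenance"), provenance)
  out
}

#' Compute every score of a catalog group
#'
#' The `_all`-style convenience entry point: computes all member scores of
#' a catalog group, in catalog order, one output column per score (plus
#' `_nm` companions where declared). Equivalent to folding
#' [compute_score()] over the group's members.
#'
#' @param data Data frame containing the union of the members' item
#'   columns.
#' @param cat A [catalog()]; supplies the definitions, sentinel missing
#'   codes, and identifier columns.
#' @param group Group identifier, e.g. `"ph_y_bp"`.
#' @param combine If `TRUE` (default), append score columns to the input;
#'   if `FALSE`, return the catalog's identifier columns plus score
#'   columns.
#' @param quiet Passed through to [compute_score()].
#' @return A tibble with one column per computed score (see
#'   [compute_score()] for the `combine` contract and provenance).
#' @examples
#' cat <- read_catalog(system.file("extdata", "catalog.yaml",
#'   package = "cohortscores"
#' ))
#' bp <- simulate_bp(n_rows = 5, seed = 1)
#' compute_group(bp, cat, "ph_y_bp", combine = FALSE)
#' @export
compute_group <- function(data, cat, group, combine = TRUE, quiet = TRUE) {
  stopifnot(is.data.frame(data), inherits(cat, "catalog"))
  if (!group %in% names(cat$groups)) {
    cs_abort(
      sprintf(
        "Unknown group '%s'. Available groups: %s.",
        group, paste(names(cat$groups), collapse = ", ")
      ),
      kind = "unknown-group"
    )
  }
  members <- cat$groups[[group]]
  if (length(members) == 0) {
    rlang::warn(sprintf("Group '%s' is empty; no scores computed.", group))
  }
  acc <- tibble::as_tibble(data)
  for (member in members) {
    acc <- compute_score(
      acc, cat$definitions[[member]],
      combine = TRUE,
      missing_codes = cat$missing_codes,
      id_cols = cat$id_columns,
      quiet = quiet
    )
  }
  if (!combine) {
    absent_ids <- setdiff(cat$id_columns, names(data))
    if (length(absent_ids) > 0) {
      cs_abort(
        sprintf(
          "Identifier column(s) absent from data: %s.",
          paste(absent_ids, collapse = ", ")
        ),
        kind = "missing-column"
      )
    }
    score_cols <- setdiff(names(acc), names(data))
    prov <- attr(acc, "provenance")
    acc <- acc[c(cat$id_columns, score_cols)]
    attr(acc, "provenance") <- prov
  }
  acc
}
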