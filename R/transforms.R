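#' Column-level data transforms
#'
#' Four generic curation utilities for rectangular score tables. All of them
#' preserve the row count, row order, and identifier columns of their input
#' exactly; they only rewrite or append columns.
#'
#' @name table-transforms
NULL

check_columns <- function(data, columns) {
  absent <- setdiff(columns, names(data))
  if (length(absent) > 0) {
    cs_abort(
      sprintf(
        "Column(s) absent from data: %s.",
        paste(absent, collapse = ", ")
      ),
      kind = "missing-column"
    )
  }
}

#' Recode the values of a column
#'
#' Values found in `mapping` are replaced by their mapped value (which may
#' be `NA`, e.g. to turn a refuse-to-answer sentinel code into missing);
#' values not in the mapping either stay as they are (`default = "keep"`)
#' or become missing (`default = "missing"`). Missing values always stay
#' missing.
#'
#' @param data A data frame.
#' @param column Name of the column to recode.
#' @param mapping A named vector or list; names are the old values (matched
#'   against `as.character()` of the column), elements the new values.
#' @param default What happens to values not named in `mapping`.
#' @return `data` with the column recoded.
#' @examples
#' d <- data.frame(x = c(1, 2, 3))
#' recode_levels(d, "x", c("3" = NA))
#' @export
recode_levels <- function(data, column, mapping,
                          default = c("keep", "missing")) {
  default <- match.arg(default)
  stopifnot(is.data.frame(data))
  check_columns(data, column)
  if (length(mapping) > 0 && is.null(names(mapping))) {
    cs_abort("`mapping` must be named by the old values.", kind = "param")
  }
  values <- data[[column]]
  keys <- as.character(values)
  observed <- !is.na(values)
  out <- values
  if (default == "missing") {
    out[observed & !(keys %in% names(mapping))] <- NA
  }
  for (old in names(mapping)) {
    out[observed & keys == old] <- mapping[[old]]
  }
  data[[column]] <- out
  data
}

#' Coalesce two columns into one
#'
#' The output column takes the first column's value wherever it is
#' observed, and otherwise the second's ("first wins"). The common use is
#' merging mutually exclusive branching-logic columns, where at most one of
#' the two is observed per row; rows where both are observed but unequal
#' are therefore counted and reported as a message, not treated as errors.
#'
#' @param data A data frame.
#' @param first,second Names of the columns to coalesce; `first` has
#'   precedence.
#' @param out Name of the output column (appended at the end).
#' @param overwrite Allow `out` to replace an existing column.
#' @param quiet Suppress the conflict message.
#' @return `data` with the coalesced column.
#' @examples
#' d <- data.frame(a = c(1, NA), b = c(NA, 2))
#' combine_cols(d, "a", "b", "ab")
#' @export
combine_cols <- function(data, first, second, out, overwrite = FALSE,
                         quiet = FALSE) {
  stopifnot(is.data.frame(data))
  check_columns(data, c(first, second))
  if (out %in% names(data) && !overwrite) {
    cs_abort(
      sprintf(
        "Output column '%s' already exists (set overwrite = TRUE to replace it).",
        out
      ),
      kind = "name-collision"
    )
  }
  v1 <- data[[first]]
  v2 <- data[[second]]
  conflicts <- sum(!is.na(v1) & !is.na(v2) & v1 != v2, na.rm = TRUE)
  if (conflicts > 0 && !quiet) {
    rlang::inform(sprintf(
      "combine_cols: %d row(s) where '%s' and '%s' disagree; kept '%s'.",
      conflicts, first, second, first
    ))
  }
  data[[out]] <- dplyr::coalesce(v1, v2)
  data
}

#' Collapse categorical levels into coarser groups
#'
#' Each old level listed in a group is replaced by the group's new level;
#' levels not listed in any group are unchanged. Groups must be pairwise
#' disjoint.
#'
#' @param data A data frame.
#' @param column Name of the column whose levels are collapsed.
#' @param level_groups A named list: names are the new levels, elements the
#'   sets of old levels they absorb.
#' @return `data` with the column collapsed.
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4))
#' combine_levels(d, "x", list("34" = c(3, 4)))
#' @export
combine_levels <- function(data, column, level_groups) {
  stopifnot(is.data.frame(data))
  check_columns(data, column)
  if (length(level_groups) > 0 && is.null(names(level_groups))) {
    cs_abort("`level_groups` must be named by the new levels.", kind = "param")
  }
  old_levels <- as.character(unlist(level_groups, use.names = FALSE))
  if (anyDuplicated(old_levels) > 0) {
    dup <- unique(old_levels[duplicated(old_levels)])
    cs_abort(
      sprintf(
        "Level group(s) overlap on old level(s): %s.",
        paste(dup, collapse = ", ")
      ),
      kind = "param"
    )
  }
  new_levels <- names(level_groups)
  # Stay numeric when the column is numeric and all new levels parse.
  if (is.numeric(data[[column]])) {
    parsed <- suppressWarnings(as.numeric(new_levels))
    if (!anyNA(parsed)) new_levels <- parsed
  }
  mapping <- list()
  for (i in seq_along(level_groups)) {
    for (old in as.character(level_groups[[i]])) {
      mapping[[old]] <- new_levels[[i]]
    }
  }
  recode_levels(data, column, mapping, default = "keep")
}

#' Make a longitudinal variable static
#'
#' Converts a variable collected at multiple study events into a single
#' per-participant constant: for each participant, one value is selected
#' and propagated to all of that participant's rows. The default rule takes
#' the value at the earliest event (by `event_order`) at which the variable
#' is observed; `rule = "baseline"` instead always takes the first event's
#' value, observed or not. Participants with no selectable value get
#' missing everywhere. The operation is idempotent.
#'
#' @param data A data frame with one row per participant x event.
#' @param column Name of the longitudinal column.
#' @param id_col,event_col Identifier columns (participant, event).
#' @param event_order Character vector giving the chronological order of
#'   event labels; defaults to the levels of a factor `event_col`. Every
#'   event label in the data must appear in it.
#' @param rule Selection rule: `"first_observed"` (default) or
#'   `"baseline"`.
#' @return `data` with the column made constant within participant.
#' @examples
#' d <- data.frame(
#'   participant_id = c("p1", "p1"), session_id = c("e1", "e2"),
#'   x = c(NA, 7)
#' )
#' make_static(d, "x", event_order = c("e1", "e2"))
#' @export
make_static <- function(data, column, id_col = "participant_id",
                        event_col = "session_id", event_order = NULL,
                        rule = c("first_observed", "baseline")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(data))
  check_columns(data, c(column, id_col, event_col))
  events <- data[[event_col]]
  event_order <- event_order %||% levels(events)
  if (is.null(event_order)) {
    cs_abort(
      "`event_order` is undefined: supply it, or use a factor event column.",
      kind = "config"
    )
  }
  rank <- match(as.character(events), event_order)
  if (anyNA(rank)) {
    bad <- unique(as.character(events)[is.na(rank)])
    cs_abort(
      sprintf(
        "Event label(s) not in `event_order`: %s.",
        paste(bad, collapse = ", ")
      ),
      kind = "config"
    )
  }
  values <- data[[column]]
  out <- values
  for (rows in split(seq_len(nrow(data)), data[[id_col]])) {
    ord <- rows[order(rank[rows])]
    v <- values[ord]
    selected <- if (rule == "baseline") {
      v[[1]]
    } else {
      obs <- v[!is.na(v)]
      if (length(obs) > 0) obs[[1]] else v[[1]][NA]
    }
    out[rows] <- selected
  }
  data[[column]] <- out
  data
}
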