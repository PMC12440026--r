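#' Define a row-level condition
#'
#' A condition specification is a predicate on one column of a score table,
#' used by [ss_count_cond()] to count, per row, how many of a list of
#' user-defined conditions hold.
#'
#' @param column Column name the condition applies to.
#' @param comparator One of `"=="`, `"!="`, `"<"`, `"<="`, `">"`, `">="`,
#'   `"in"`, `"not-in"`.
#' @param reference A scalar for the ordering/equality comparators, or a
#'   vector of values for `"in"`/`"not-in"`.
#' @param missing_policy How the condition evaluates on a missing value:
#'   `"false"` (the default; the condition simply does not hold) or
#'   `"missing"` (missingness propagates, making the row's count missing).
#'
#' @return A `cond_spec` object.
#' @examples
#' cond_spec("age", ">=", 10)
#' cond_spec("group", "in", c("a", "b"))
#' @export
cond_spec <- function(column, comparator, reference,
                      missing_policy = c("false", "missing")) {
  comparators <- c("==", "!=", "<", "<=", ">", ">=", "in", "not-in")
  if (!is.character(column) || length(column) != 1 || !nzchar(column)) {
    cs_abort("`column` must be a single column name.", kind = "param")
  }
  if (!comparator %in% comparators) {
    cs_abort(
      sprintf(
        "Unknown comparator '%s' (expected one of %s).",
        comparator, paste(comparators, collapse = ", ")
      ),
      kind = "param"
    )
  }
  set_valued <- comparator %in% c("in", "not-in")
  if (set_valued) {
    if (length(reference) < 1) {
      cs_abort(
        sprintf("Comparator '%s' requires a non-empty value set.", comparator),
        kind = "param"
      )
    }
  } else if (length(reference) != 1) {
    cs_abort(
      sprintf("Comparator '%s' requires a scalar reference.", comparator),
      kind = "param"
    )
  }
  missing_policy <- match.arg(missing_policy)
  structure(
    list(
      column = column, comparator = comparator, reference = reference,
      missing_policy = missing_policy
    ),
    class = "cond_spec"
  )
}

#' @export
print.cond_spec <- function(x, ...) {
  ref <- paste(format(x$reference), collapse = ", ")
  if (x$comparator %in% c("in", "not-in")) ref <- paste0("{", ref, "}")
  cat(
    "<cond_spec> ", x$column, " ", x$comparator, " ", ref,
    " [missing: ", x$missing_policy, "]\n",
    sep = ""
  )
  invisible(x)
}

# Evaluate one condition against a vector, returning logical (NA allowed
# only under the "missing" policy).
eval_cond <- function(cond, values) {
  res <- switch(cond$comparator,
    "==" = values == cond$reference,
    "!=" = values != cond$reference,
    "<" = values < cond$reference,
    "<=" = values <= cond$reference,
    ">" = values > cond$reference,
    ">=" = values >= cond$reference,
    "in" = values %in% cond$reference,
    "not-in" = !(values %in% cond$reference)
  )
  miss <- is.na(values)
  res[miss] <- if (cond$missing_policy == "missing") NA else FALSE
  res
}
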