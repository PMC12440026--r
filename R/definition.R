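KERNELS <- c(
  "ss_mean", "ss_sum", "ss_nm", "ss_count", "ss_count_cond",
  "ss_max", "ss_prsum", "ss_mean_pos", "ss_tscore"
)
KERNELS_WITH_MAX_NA <- c("ss_mean", "ss_sum", "ss_prsum", "ss_max")
KERNELS_WITH_NM_DEFAULT <- c("ss_mean", "ss_sum", "ss_prsum")

new_report <- function() {
  structure(
    tibble::tibble(
      kind = character(), field = character(), message = character()
    ),
    class = c("cs_report", "tbl_df", "tbl", "data.frame")
  )
}

report_add <- function(report, kind, field, message) {
  out <- dplyr::bind_rows(
    report,
    tibble::tibble(kind = kind, field = field, message = message)
  )
  class(out) <- class(new_report())
  out
}

#' @export
print.cs_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation report> no violations\n")
  } else {
    cat("<validation report>", nrow(x), "violation(s)\n")
    for (i in seq_len(nrow(x))) {
      cat("  [", x$kind[[i]], "] ", x$field[[i]], ": ", x$message[[i]], "\n",
        sep = ""
      )
    }
  }
  invisible(x)
}

#' Declare a summary score
#'
#' A score definition is the declarative unit the engine executes: the
#' score's name (parsed by the naming grammar), the item columns it reads,
#' the scoring kernel that reduces each row of items to a value, and the
#' kernel's parameters. Construction is permissive — value-level problems
#' (e.g. `max_na` exceeding the item count, or a missing required
#' parameter) are reported by [validate_definition()], not raised here, so
#' whole catalogs can be checked in one pass.
#'
#' @param name Score name string (or a parsed `score_name`), e.g.
#'   `"fc_p_fes__cohes_mean"`.
#' @param items Character vector of item column names, in order.
#' @param kernel One of the nine kernel identifiers: `ss_mean`, `ss_sum`,
#'   `ss_nm`, `ss_count`, `ss_count_cond`, `ss_max`, `ss_prsum`,
#'   `ss_mean_pos`, `ss_tscore`.
#' @param max_na Maximum number of missing items tolerated (kernels
#'   `ss_mean`, `ss_sum`, `ss_prsum`, `ss_max`); default 0.
#' @param target_levels Values counted by the `ss_count` kernel.
#' @param conditions List of [cond_spec()] for the `ss_count_cond` kernel.
#' @param norms A [norm_table()] for the `ss_tscore` kernel.
#' @param stratum_cols Data columns holding the norm strata for
#'   `ss_tscore`.
#' @param nm_companion Whether a sibling `_nm` (number-missing) score is
#'   derived alongside this score. Defaults to `TRUE` for the mean / sum /
#'   prorated-sum kernels, which conventionally ship with an `_nm`
#'   companion, and `FALSE` otherwise.
#'
#' @return A `score_definition` object.
#' @examples
#' score_definition(
#'   "fc_p_fes__cohes_mean",
#'   items = sprintf("fc_p_fes__cohes_%03d", 1:9),
#'   kernel = "ss_mean", max_na = 1
#' )
#' @export
score_definition <- function(name, items, kernel,
                             max_na = NULL, target_levels = NULL,
                             conditions = NULL, norms = NULL,
                             stratum_cols = NULL, nm_companion = NULL) {
  if (!inherits(name, "score_name")) name <- parse_score_name(name)
  if (!is.character(kernel) || length(kernel) != 1 || !kernel %in% KERNELS) {
    cs_abort(
      sprintf(
        "Unknown kernel '%s' (expected one of %s).",
        paste(format(kernel), collapse = ", "), paste(KERNELS, collapse = ", ")
      ),
      kind = "param"
    )
  }
  if (is.null(max_na) && kernel %in% KERNELS_WITH_MAX_NA) max_na <- 0L
  if (!is.null(max_na)) max_na <- as.integer(max_na)
  nm_companion <- nm_companion %||% (kernel %in% KERNELS_WITH_NM_DEFAULT)
  structure(
    list(
      name = name,
      items = as.character(items),
      kernel = kernel,
      max_na = max_na,
      target_levels = target_levels,
      conditions = conditions,
      norms = norms,
      stratum_cols = stratum_cols,
      nm_companion = isTRUE(nm_companion)
    ),
    class = "score_definition"
  )
}

#' @export
print.score_definition <- function(x, ...) {
  cat("<score_definition> ", render_score_name(x$name), "\n", sep = "")
  cat("  kernel: ", x$kernel, "; items: ", length(x$items), sep = "")
  if (!is.null(x$max_na)) cat("; max_na: ", x$max_na, sep = "")
  if (x$nm_companion) cat("; nm companion")
  cat("\n")
  invisible(x)
}

#' Validate a score definition
#'
#' Checks the value-level invariants of a [score_definition()] and returns
#' a report of violations rather than raising, so that an entire catalog
#' can be validated in one pass. An empty report means the definition is
#' valid.
#'
#' @param defn A [score_definition()].
#' @return A validation report: a tibble with columns `kind`, `field`, and
#'   `message`, one row per violation.
#' @examples
#' defn <- score_definition("fc_p_fes__cohes_mean",
#'   items = sprintf("fc_p_fes__cohes_%03d", 1:9),
#'   kernel = "ss_mean", max_na = 12
#' )
#' validate_definition(defn)
#' @export
validate_definition <- function(defn) {
  stopifnot(inherits(defn, "score_definition"))
  report <- new_report()
  if (length(defn$items) == 0) {
    report <- report_add(report, "param", "items", "items must be non-empty")
  }
  if (anyDuplicated(defn$items) > 0) {
    dup <- unique(defn$items[duplicated(defn$items)])
    report <- report_add(
      report, "param", "items",
      sprintf("duplicate item(s): %s", paste(dup, collapse = ", "))
    )
  }
  if (!is.null(defn$max_na)) {
    if (is.na(defn$max_na) || defn$max_na < 0) {
      report <- report_add(
        report, "param", "max_na", "max_na must be a non-negative integer"
      )
    } else if (defn$max_na > length(defn$items)) {
      report <- report_add(
        report, "param", "max_na",
        sprintf(
          "max_na exceeds item count (max_na = %d, items = %d)",
          defn$max_na, length(defn$items)
        )
      )
    }
  }
  if (defn$kernel == "ss_count" && is.null(defn$target_levels)) {
    report <- report_add(
      report, "param", "target_levels",
      "kernel ss_count requires `target_levels`"
    )
  }
  if (defn$kernel == "ss_count_cond") {
    if (is.null(defn$conditions)) {
      report <- report_add(
        report, "param", "conditions",
        "kernel ss_count_cond requires `conditions`"
      )
    } else if (!all(vapply(defn$conditions, inherits, logical(1), "cond_spec"))) {
      report <- report_add(
        report, "type", "conditions",
        "`conditions` must be a list of cond_spec objects"
      )
    }
  }
  if (defn$kernel == "ss_tscore") {
    if (is.null(defn$norms)) {
      report <- report_add(
        report, "param", "norms", "kernel ss_tscore requires `norms`"
      )
    } else if (!inherits(defn$norms, "norm_table")) {
      report <- report_add(
        report, "type", "norms", "`norms` must be a norm_table"
      )
    } else {
      needed <- attr(defn$norms, "stratum_cols")
      if (length(needed) > 0 &&
        !all(needed %in% (defn$stratum_cols %||% character()))) {
        report <- report_add(
          report, "param", "stratum_cols",
          sprintf(
            "norm table is stratified by %s but `stratum_cols` does not cover it",
            paste(needed, collapse = ", ")
          )
        )
      }
    }
    if (length(defn$items) != 1) {
      report <- report_add(
        report, "param", "items",
        "kernel ss_tscore takes exactly one item column (the raw score)"
      )
    }
  }
  report
}

#' Default output column name of a score definition
#'
#' The rendered form of the definition's own score name — the name the
#' computed column gets when the caller does not override it.
#'
#' @param defn A valid [score_definition()].
#' @return A single string.
#' @export
default_score_name <- function(defn) {
  stopifnot(inherits(defn, "score_definition"))
  render_score_name(defn$name)
}
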