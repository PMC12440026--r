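#' Row-wise scoring kernels
#'
#' The `ss_*` family implements the generic summary-score computations every
#' catalog score is built from. Each kernel is defined on one row's item
#' values with an explicit missingness contract; all kernels are also
#' vectorized over the rows of a matrix or data frame of item columns.
#'
#' Missingness contract (writing `nm` for the number of missing items in a
#' row and `n` for the number of items):
#'
#' * [ss_nm()] returns `nm` itself; it is always defined.
#' * [ss_mean()], [ss_sum()], [ss_prsum()], and [ss_max()] return their
#'   statistic over the observed items when `nm <= max_na` **and** at least
#'   one item is observed; otherwise they return missing. An all-missing row
#'   is missing even when `max_na >= n`, since a score computed from zero
#'   items is undefined.
#' * [ss_prsum()] prorates the observed sum by `n / (n - nm)`, the standard
#'   psychometric estimate of the full-scale sum under partial missingness;
#'   with no missing items it equals [ss_sum()] exactly.
#' * [ss_mean_pos()] averages the observed items strictly greater than zero
#'   and is missing when no such item exists.
#' * [ss_count()] counts observed items falling in `target_levels`; missing
#'   items contribute zero, so the count is a lower bound, and the result is
#'   missing only when every item is missing.
#' * [ss_count_cond()] counts how many of a list of [cond_spec()] predicates
#'   hold for a row; a predicate on a missing value follows its
#'   `missing_policy`.
#' * [ss_tscore()] converts a raw score to a t-score by exact lookup in a
#'   [norm_table()]; a missing raw score propagates to a missing t-score.
#'
#' No rounding is applied anywhere; full floating-point values are returned.
#'
#' @param x Item values: a numeric vector (one row, returning a scalar) or a
#'   matrix / data frame with one column per item (returning one value per
#'   row).
#' @param max_na Maximum number of missing items tolerated before the score
#'   is set to missing. Must satisfy `0 <= max_na <= n_items`.
#'
#' @return A scalar for vector input, otherwise a vector with one element
#'   per row of `x`.
#'
#' @examples
#' ss_mean(c(1, 2, NA, 4), max_na = 1)
#' ss_prsum(c(2, 2, NA, 2), max_na = 1) # 6 * 4/3 = 8
#' ss_nm(rbind(c(1, NA, 3), c(NA, NA, NA)))
#' @name scoring-kernels
NULL

# Normalize kernel input to a matrix of item rows. A bare atomic vector is
# one observation; result carries whether to drop back to a scalar.
as_item_rows <- function(x, numeric = TRUE, arg = "x") {
  scalar <- FALSE
  if (is.data.frame(x)) {
    m <- as.matrix(x)
  } else if (is.matrix(x)) {
    m <- x
  } else if (is.atomic(x) && !is.null(x)) {
    m <- matrix(x, nrow = 1)
    scalar <- TRUE
  } else {
    cs_abort(
      sprintf("`%s` must be a vector, matrix, or data frame of items.", arg),
      kind = "type"
    )
  }
  if (ncol(m) < 1) {
    cs_abort(sprintf("`%s` must contain at least one item.", arg), kind = "param")
  }
  if (numeric) {
    if (is.logical(m)) storage.mode(m) <- "double"
    if (!is.numeric(m)) {
      cs_abort(
        sprintf("`%s` must contain numeric item values.", arg),
        kind = "type"
      )
    }
  }
  list(m = m, scalar = scalar)
}

check_max_na <- function(max_na, n_items) {
  if (!is.numeric(max_na) || length(max_na) != 1 || is.na(max_na) ||
    max_na != as.integer(max_na) || max_na < 0 || max_na > n_items) {
    cs_abort(
      sprintf(
        "`max_na` must be a single integer with 0 <= max_na <= %d (the number of items), got %s.",
        n_items, paste(format(max_na), collapse = ", ")
      ),
      kind = "param"
    )
  }
  as.integer(max_na)
}

drop_scalar <- function(values, scalar) if (scalar) values[[1]] else values

# Shared missingness gate: rows with nm > max_na, or with no observed item
# at all, get a missing score.
mask_missing <- function(values, nm, n_items, max_na) {
  values[nm > max_na | nm == n_items] <- NA
  values
}

#' @rdname scoring-kernels
#' @export
ss_nm <- function(x) {
  items <- as_item_rows(x, numeric = FALSE)
  nm <- as.integer(rowSums(is.na(items$m)))
  drop_scalar(nm, items$scalar)
}

#' @rdname scoring-kernels
#' @export
ss_mean <- function(x, max_na = 0) {
  items <- as_item_rows(x)
  n <- ncol(items$m)
  max_na <- check_max_na(max_na, n)
  nm <- rowSums(is.na(items$m))
  out <- rowMeans(items$m, na.rm = TRUE)
  out <- mask_missing(out, nm, n, max_na)
  drop_scalar(as.numeric(out), items$scalar)
}

#' @rdname scoring-kernels
#' @export
ss_sum <- function(x, max_na = 0) {
  items <- as_item_rows(x)
  n <- ncol(items$m)
  max_na <- check_max_na(max_na, n)
  nm <- rowSums(is.na(items$m))
  out <- rowSums(items$m, na.rm = TRUE)
  out <- mask_missing(out, nm, n, max_na)
  drop_scalar(as.numeric(out), items$scalar)
}

#' @rdname scoring-kernels
#' @export
ss_prsum <- function(x, max_na = 0) {
  items <- as_item_rows(x)
  n <- ncol(items$m)
  max_na <- check_max_na(max_na, n)
  nm <- rowSums(is.na(items$m))
  # factor is exactly 1 when nm = 0, so prsum == sum bit-for-bit there
  out <- rowSums(items$m, na.rm = TRUE) * (n / (n - nm))
  out <- mask_missing(out, nm, n, max_na)
  drop_scalar(as.numeric(out), items$scalar)
}

#' @rdname scoring-kernels
#' @export
ss_max <- function(x, max_na = 0) {
  items <- as_item_rows(x)
  n <- ncol(items$m)
  max_na <- check_max_na(max_na, n)
  nm <- rowSums(is.na(items$m))
  cols <- lapply(seq_len(n), function(j) items$m[, j])
  out <- do.call(pmax, c(cols, list(na.rm = TRUE)))
  out <- mask_missing(out, nm, n, max_na)
  drop_scalar(as.numeric(out), items$scalar)
}

#' @rdname scoring-kernels
#' @export
ss_mean_pos <- function(x) {
  items <- as_item_rows(x)
  m <- items$m
  m[!is.na(m) & m <= 0] <- NA
  n_pos <- rowSums(!is.na(m))
  out <- rowMeans(m, na.rm = TRUE)
  out[n_pos == 0] <- NA_real_
  drop_scalar(as.numeric(out), items$scalar)
}

#' @rdname scoring-kernels
#' @param target_levels Values counted by [ss_count()].
#' @export
ss_count <- function(x, target_levels) {
  if (missing(target_levels) || length(target_levels) < 1) {
    cs_abort("`target_levels` must be a non-empty set of values.", kind = "param")
  }
  items <- as_item_rows(x, numeric = FALSE)
  m <- items$m
  hits <- matrix(m %in% target_levels, nrow = nrow(m))
  out <- as.integer(rowSums(hits))
  out[rowSums(is.na(m)) == ncol(m)] <- NA_integer_
  drop_scalar(out, items$scalar)
}

#' @rdname scoring-kernels
#' @param data For [ss_count_cond()]: a data frame, or a named list holding
#'   one row.
#' @param conditions A list of [cond_spec()] objects (possibly empty).
#' @export
ss_count_cond <- function(data, conditions) {
  scalar <- FALSE
  if (is.list(data) && !is.data.frame(data)) {
    data <- tibble::as_tibble(data)
    scalar <- TRUE
  }
  if (!is.data.frame(data)) {
    cs_abort("`data` must be a data frame or a named list.", kind = "type")
  }
  if (inherits(conditions, "cond_spec")) conditions <- list(conditions)
  if (!is.list(conditions) ||
    !all(vapply(conditions, inherits, logical(1), "cond_spec"))) {
    cs_abort("`conditions` must be a list of cond_spec objects.", kind = "type")
  }
  unknown <- setdiff(
    vapply(conditions, function(cond) cond$column, character(1)),
    names(data)
  )
  if (length(unknown) > 0) {
    cs_abort(
      sprintf(
        "Condition column(s) absent from data: %s.",
        paste(unique(unknown), collapse = ", ")
      ),
      kind = "missing-column"
    )
  }
  if (length(conditions) == 0) {
    return(drop_scalar(rep(0L, nrow(data)), scalar))
  }
  res <- vapply(
    conditions,
    function(cond) eval_cond(cond, data[[cond$column]]),
    logical(nrow(data))
  )
  res <- matrix(res, nrow = nrow(data))
  out <- as.integer(rowSums(res)) # NA when a missing-propagating cond fired
  drop_scalar(out, scalar)
}

#' @rdname scoring-kernels
#' @param raw For [ss_tscore()]: numeric raw score(s) to convert.
#' @param norms A [norm_table()].
#' @param stratum The stratum to look up in: a named list / vector (one
#'   stratum for all raw scores) or a data frame with one row per raw score.
#'   Omit for a norm table with a single global stratum.
#' @export
ss_tscore <- function(raw, norms, stratum = NULL) {
  if (!inherits(norms, "norm_table")) {
    cs_abort("`norms` must be a norm_table.", kind = "type")
  }
  if (!is.numeric(raw) && !all(is.na(raw))) {
    cs_abort("`raw` must be numeric.", kind = "type")
  }
  stratum_cols <- attr(norms, "stratum_cols")
  if (length(stratum_cols) == 0) {
    stratum_df <- tibble::tibble(.rows = length(raw))
  } else {
    if (is.null(stratum)) {
      cs_abort(
        sprintf(
          "Norm table is stratified by %s; supply `stratum`.",
          paste(stratum_cols, collapse = ", ")
        ),
        kind = "param"
      )
    }
    if (!is.data.frame(stratum)) stratum <- tibble::as_tibble(as.list(stratum))
    missing_cols <- setdiff(stratum_cols, names(stratum))
    if (length(missing_cols) > 0) {
      cs_abort(
        sprintf(
          "`stratum` lacks column(s): %s.",
          paste(missing_cols, collapse = ", ")
        ),
        kind = "missing-column"
      )
    }
    stratum_df <- stratum[stratum_cols]
    if (nrow(stratum_df) == 1 && length(raw) > 1) {
      stratum_df <- stratum_df[rep(1L, length(raw)), , drop = FALSE]
    }
    if (nrow(stratum_df) != length(raw)) {
      cs_abort(
        "`stratum` must describe one stratum, or one row per raw score.",
        kind = "param"
      )
    }
    known <- unique(norm_stratum_key(norms[stratum_cols]))
    got <- norm_stratum_key(stratum_df)
    if (any(!got %in% known & !is.na(raw))) {
      bad <- stratum_df[which(!got %in% known & !is.na(raw))[1], , drop = FALSE]
      cs_abort(
        sprintf(
          "Stratum (%s) not present in the norm table.",
          paste(names(bad), unlist(lapply(bad, as.character)),
            sep = " = ", collapse = ", "
          )
        ),
        kind = "param"
      )
    }
  }

  keys <- norm_key(stratum_df, raw)
  idx <- match(keys, norm_key(norms[stratum_cols], norms$raw))
  bad <- which(is.na(idx) & !is.na(raw))
  if (length(bad) > 0) {
    cs_abort(
      sprintf(
        "Raw score %s is outside the norm table's domain for stratum (%s).",
        format(raw[bad[1]]),
        if (length(stratum_cols) == 0) {
          "global"
        } else {
          paste(stratum_cols,
            unlist(lapply(stratum_df[bad[1], , drop = FALSE], as.character)),
            sep = " = ", collapse = ", "
          )
        }
      ),
      kind = "param"
    )
  }
  out <- norms$t[idx]
  out[is.na(raw)] <- NA_real_
  out
}
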