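#' Normative lookup tables for t-score conversion
#'
#' A norm table maps a raw summary score, within a demographic stratum
#' (e.g. age band x sex; or a single global stratum), to a normatively
#' standardized t-score (conventionally mean 50, SD 10). [ss_tscore()]
#' performs an exact lookup against such a table; no interpolation is done,
#' and a raw score outside the table's domain is an error rather than a
#' silent missing value.
#'
#' @param entries A data frame with one row per (stratum, raw score)
#'   combination, containing the stratum columns plus numeric columns
#'   `raw` and `t`.
#' @param stratum_cols Character vector naming the stratum columns of
#'   `entries` (empty for a single global stratum). Defaults to every
#'   column other than `raw` and `t`.
#'
#' @return A `norm_table`: a tibble with attribute `stratum_cols`.
#' @examples
#' norm_table(data.frame(raw = 0:3, t = c(35, 45, 55, 65)))
#' @export
norm_table <- function(entries, stratum_cols = NULL) {
  entries <- tibble::as_tibble(entries)
  if (!all(c("raw", "t") %in% names(entries))) {
    cs_abort("Norm entries must contain columns `raw` and `t`.", kind = "param")
  }
  stratum_cols <- stratum_cols %||% setdiff(names(entries), c("raw", "t"))
  missing_cols <- setdiff(stratum_cols, names(entries))
  if (length(missing_cols) > 0) {
    cs_abort(
      sprintf(
        "Stratum column(s) absent from norm entries: %s.",
        paste(missing_cols, collapse = ", ")
      ),
      kind = "missing-column"
    )
  }
  if (!is.numeric(entries$t) || any(!is.finite(entries$t))) {
    cs_abort("Norm t-scores must be finite numerics.", kind = "type")
  }
  keys <- norm_key(entries[stratum_cols], entries$raw)
  if (anyDuplicated(keys) > 0) {
    cs_abort(
      "Norm entries must be unique per (stratum, raw score).",
      kind = "param"
    )
  }
  structure(
    entries[c(stratum_cols, "raw", "t")],
    stratum_cols = stratum_cols,
    class = c("norm_table", class(entries))
  )
}

# Canonical string key for a (stratum, raw) pair.
norm_key <- function(stratum_df, raw) {
  parts <- c(
    lapply(stratum_df, as.character),
    list(as.character(raw))
  )
  do.call(paste, c(parts, sep = "\r"))
}

norm_stratum_key <- function(stratum_df) {
  if (ncol(stratum_df) == 0) {
    return(rep("", nrow(stratum_df)))
  }
  do.call(paste, c(lapply(stratum_df, as.character), sep = "\r"))
}

#' Read a norm table from a delimited file
#'
#' Expects a CSV/TSV file with numeric columns `raw` and `t`; any other
#' columns are taken as stratum columns unless `stratum_cols` says
#' otherwise.
#'
#' @param path Path to a `.csv` or `.tsv` file.
#' @param stratum_cols Optional explicit stratum column names.
#' @return A [norm_table()].
#' @export
read_norm_table <- function(path, stratum_cols = NULL) {
  if (!file.exists(path)) {
    cs_abort(sprintf("Norm table file not found: %s.", path), kind = "io")
  }
  ext <- tolower(tools::file_ext(path))
  entries <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE, na = "", progress = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE, na = "", progress = FALSE),
    cs_abort(
      sprintf("Norm tables must be .csv or .tsv files (got '%s').", path),
      kind = "io"
    )
  )
  norm_table(entries, stratum_cols = stratum_cols)
}
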