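#' Score-naming grammar
#'
#' Summary scores follow a hierarchical naming convention used throughout
#' large cohort tabulated-data releases:
#'
#' ```
#' <domain>_<respondent>_<table>(__<scale_segment>)*_<suffix>
#' ```
#'
#' A single underscore separates the domain code, respondent code, table
#' code, and final suffix; each scale/subscale segment is introduced by a
#' double underscore. For example `fc_p_fes__cohes_mean` is the mean of the
#' items of the parent-report family-environment cohesion subscale, and
#' `ph_y_bp__sys_nm` is the number of missing systolic blood-pressure
#' readings. The domain vocabulary has seven codes: `ab` (general), `fc`
#' (family, friends & community), `mh` (mental health), `nc`
#' (neurocognition), `nt` (novel technologies), `ph` (physical health), and
#' `su` (substance use).
#'
#' @name score-name-grammar
#' @keywords internal
NULL

# Seven-domain vocabulary; the suffix vocabulary mirrors the scoring kernels.
DOMAIN_CODES <- c("ab", "fc", "mh", "nc", "nt", "ph", "su")
SCORE_SUFFIXES <- c("mean", "sum", "nm", "count", "max", "prsum", "tscore")

new_score_name <- function(domain, respondent, table, scale_path, suffix) {
  structure(
    list(
      domain = domain, respondent = respondent, table = table,
      scale_path = as.character(scale_path), suffix = suffix
    ),
    class = "score_name"
  )
}

#' Parse a score name into its grammatical components
#'
#' @param raw A single score-name string, e.g. `"fc_p_fes__cohes_mean"`.
#' @param extra_suffixes Additional suffix tokens (beyond
#'   `mean, sum, nm, count, max, prsum, tscore`) accepted by the parser,
#'   e.g. suffixes declared by a catalog.
#'
#' @return A `score_name` object: a list with fields `domain`, `respondent`,
#'   `table`, `scale_path` (character vector, possibly empty), and `suffix`.
#'   `render_score_name()` is its exact inverse.
#'
#' @examples
#' parse_score_name("fc_p_fes__cohes_mean")
#' parse_score_name("ph_y_bp__sys_nm")
#' @export
parse_score_name <- function(raw, extra_suffixes = character()) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw) || !nzchar(raw)) {
    cs_abort("`raw` must be a single non-empty string.", kind = "parse")
  }
  if (grepl("[^a-z0-9_]", raw)) {
    cs_abort(
      sprintf("Score name '%s' contains characters outside [a-z0-9_].", raw),
      kind = "parse"
    )
  }
  suffixes <- c(SCORE_SUFFIXES, extra_suffixes)
  chunks <- strsplit(raw, "__", fixed = TRUE)[[1]]
  if (any(!nzchar(chunks))) {
    cs_abort(
      sprintf("Score name '%s' has an empty scale segment.", raw),
      kind = "parse"
    )
  }

  head_toks <- strsplit(chunks[[1]], "_", fixed = TRUE)[[1]]
  if (any(!nzchar(head_toks))) {
    cs_abort(
      sprintf("Score name '%s' has an empty token.", raw),
      kind = "parse"
    )
  }

  if (length(chunks) == 1) {
    # No scale segments: exactly <domain>_<respondent>_<table>_<suffix>.
    if (length(head_toks) != 4) {
      cs_abort(
        sprintf(
          "Score name '%s' must have the form %s.",
          raw, "<domain>_<respondent>_<table>(__<scale>)*_<suffix>"
        ),
        kind = "parse"
      )
    }
    parts <- list(
      domain = head_toks[[1]], respondent = head_toks[[2]],
      table = head_toks[[3]], scale_path = character(), suffix = head_toks[[4]]
    )
  } else {
    if (length(head_toks) != 3) {
      cs_abort(
        sprintf(
          "Score name '%s': segment '%s' must be <domain>_<respondent>_<table>.",
          raw, chunks[[1]]
        ),
        kind = "parse"
      )
    }
    last_toks <- strsplit(chunks[[length(chunks)]], "_", fixed = TRUE)[[1]]
    if (any(!nzchar(last_toks))) {
      cs_abort(
        sprintf("Score name '%s' has an empty token.", raw),
        kind = "parse"
      )
    }
    if (length(last_toks) < 2) {
      cs_abort(
        sprintf(
          "Score name '%s': segment '%s' lacks either a scale token or a suffix.",
          raw, chunks[[length(chunks)]]
        ),
        kind = "parse"
      )
    }
    mid <- chunks[-c(1, length(chunks))]
    parts <- list(
      domain = head_toks[[1]], respondent = head_toks[[2]],
      table = head_toks[[3]],
      scale_path = c(
        mid,
        paste(last_toks[-length(last_toks)], collapse = "_")
      ),
      suffix = last_toks[[length(last_toks)]]
    )
  }

  if (!parts$domain %in% DOMAIN_CODES) {
    cs_abort(
      sprintf(
        "Score name '%s': unknown domain '%s' (expected one of %s).",
        raw, parts$domain, paste(DOMAIN_CODES, collapse = ", ")
      ),
      kind = "parse"
    )
  }
  if (!parts$suffix %in% suffixes) {
    cs_abort(
      sprintf(
        "Score name '%s': unknown suffix '%s' (expected one of %s).",
        raw, parts$suffix, paste(suffixes, collapse = ", ")
      ),
      kind = "parse"
    )
  }
  new_score_name(
    parts$domain, parts$respondent, parts$table, parts$scale_path,
    parts$suffix
  )
}

#' Render a parsed score name back to its string form
#'
#' Exact inverse of [parse_score_name()]:
#' `render_score_name(parse_score_name(s)) == s` for every valid `s`.
#'
#' @param name A `score_name` object.
#' @return A single string.
#' @export
render_score_name <- function(name) {
  stopifnot(inherits(name, "score_name"))
  stem <- paste(name$domain, name$respondent, name$table, sep = "_")
  if (length(name$scale_path) == 0) {
    return(paste(stem, name$suffix, sep = "_"))
  }
  paste0(
    stem,
    paste0("__", name$scale_path, collapse = ""),
    "_", name$suffix
  )
}

# Rebuild the same name with a different suffix (used for `_nm` companions).
score_name_sibling <- function(name, suffix) {
  new_score_name(
    name$domain, name$respondent, name$table, name$scale_path, suffix
  )
}

#' @export
format.score_name <- function(x, ...) render_score_name(x)

#' @export
print.score_name <- function(x, ...) {
  cat("<score_name> ", render_score_name(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.score_name <- function(x, ...) render_score_name(x)
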