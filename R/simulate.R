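#' Describe a missingness pattern for simulated items
#'
#' Either an exact per-row count of missing items (recycled over rows) or a
#' global per-cell missing probability. Exactly one of the two modes may be
#' set.
#'
#' @param per_row Integer vector of missing-item counts per row (recycled
#'   to the table's row count); each count must not exceed the item count.
#' @param prob Per-cell probability of missingness in `[0, 1]`.
#' @param seed Integer seed governing where the missing cells are placed.
#' @return A `missingness_pattern` object.
#' @examples
#' missingness_pattern(per_row = c(0, 1, 2), seed = 1)
#' missingness_pattern(prob = 0.05, seed = 1)
#' @export
missingness_pattern <- function(per_row = NULL, prob = NULL, seed = 1L) {
  if (is.null(per_row) == is.null(prob)) {
    cs_abort(
      "Set exactly one of `per_row` (exact counts) or `prob` (probability).",
      kind = "config"
    )
  }
  if (!is.null(prob) && (prob < 0 || prob > 1)) {
    cs_abort("`prob` must lie in [0, 1].", kind = "config")
  }
  if (!is.null(per_row) && any(per_row < 0)) {
    cs_abort("`per_row` counts must be non-negative.", kind = "config")
  }
  structure(
    list(
      per_row = if (!is.null(per_row)) as.integer(per_row),
      prob = prob,
      seed = as.integer(seed)
    ),
    class = "missingness_pattern"
  )
}

id_frame <- function(n_rows) {
  tibble::tibble(
    participant_id = sprintf("sub%04d", seq_len(n_rows)),
    session_id = "event_01"
  )
}

apply_missingness <- function(items, pattern) {
  n_rows <- nrow(items)
  n_items <- ncol(items)
  withr::with_seed(pattern$seed, {
    if (!is.null(pattern$per_row)) {
      counts <- rep_len(pattern$per_row, n_rows)
      if (any(counts > n_items)) {
        cs_abort(
          sprintf(
            "Per-row missing count exceeds the %d available items.", n_items
          ),
          kind = "config"
        )
      }
      for (i in seq_len(n_rows)) {
        if (counts[[i]] > 0) {
          items[i, sample.int(n_items, counts[[i]])] <- NA
        }
      }
    } else {
      mask <- matrix(
        runif(n_rows * n_items) < pattern$prob,
        nrow = n_rows
      )
      items[mask] <- NA
    }
  })
  items
}

#' Simulate a table of Likert-type item responses
#'
#' Generates a score table shaped like the raw input of a questionnaire
#' subscale: identifier columns plus item columns named
#' `<prefix>_001 ... <prefix>_NNN` (zero-padded to three digits), with
#' values drawn uniformly from `levels` and missingness placed according
#' to `pattern`. Fully reproducible from the seeds.
#'
#' @param n_rows,n_items Table dimensions (both positive).
#' @param levels Values the items are drawn from (default binary `0:1`,
#'   true/false-style items).
#' @param pattern A [missingness_pattern()], or `NULL` for fully observed
#'   items.
#' @param prefix Item-column prefix, e.g. `"fc_p_fes__cohes"`.
#' @param seed Integer seed for the item values.
#' @return A tibble with `participant_id`, `session_id`, and the item
#'   columns.
#' @examples
#' simulate_items(
#'   n_rows = 4, n_items = 9,
#'   pattern = missingness_pattern(per_row = c(0, 1, 2, 0), seed = 7),
#'   prefix = "fc_p_fes__cohes", seed = 7
#' )
#' @export
simulate_items <- function(n_rows, n_items, levels = 0:1, pattern = NULL,
                           prefix = "fc_p_fes__cohes", seed = 1L) {
  stopifnot(n_rows >= 1, n_items >= 1)
  values <- withr::with_seed(as.integer(seed), {
    matrix(
      sample(levels, n_rows * n_items, replace = TRUE),
      nrow = n_rows
    )
  })
  if (!is.null(pattern)) {
    stopifnot(inherits(pattern, "missingness_pattern"))
    values <- apply_missingness(values, pattern)
  }
  colnames(values) <- sprintf("%s_%03d", prefix, seq_len(n_items))
  dplyr::bind_cols(id_frame(n_rows), tibble::as_tibble(values))
}

#' Simulate a youth blood-pressure table
#'
#' Generates the raw input of the blood-pressure measure: three replicate
#' readings each of systolic pressure (`ph_y_bp__sys_001..003`, mmHg),
#' diastolic pressure (`ph_y_bp__dia_001..003`, mmHg), and heart rate
#' (`ph_y_bp__hrate_001..003`, bpm), in ranges plausible for early
#' adolescents. With `missing_prob > 0`, readings are dropped
#' independently at that rate.
#'
#' @param n_rows Number of participants.
#' @param seed Integer seed.
#' @param missing_prob Per-reading probability of missingness (default 0:
#'   all readings observed).
#' @return A tibble with the identifier columns and 9 measurement columns.
#' @examples
#' simulate_bp(n_rows = 5, seed = 1)
#' @export
simulate_bp <- function(n_rows, seed = 1L, missing_prob = 0) {
  stopifnot(n_rows >= 1)
  withr::with_seed(as.integer(seed), {
    person <- list(sys = rnorm(n_rows, 110, 9), dia = rnorm(n_rows, 65, 7),
      hrate = rnorm(n_rows, 80, 9))
    cols <- list()
    for (measure in names(person)) {
      for (rep_i in 1:3) {
        col <- sprintf("ph_y_bp__%s_%03d", measure, rep_i)
        cols[[col]] <- round(person[[measure]] + rnorm(n_rows, 0, 3))
      }
    }
    out <- dplyr::bind_cols(id_frame(n_rows), tibble::as_tibble(cols))
    if (missing_prob > 0) {
      for (col in setdiff(names(out), c("participant_id", "session_id"))) {
        out[[col]][runif(n_rows) < missing_prob] <- NA
      }
    }
    out
  })
}

#' Simulate a longitudinal table
#'
#' Generates one row per participant x event, with a numeric variable
#' `ab_p_demo__years` that drifts across events and is sometimes missing —
#' the shape of input [make_static()] is designed for.
#'
#' @param n_participants Number of participants.
#' @param events Ordered character vector of event labels.
#' @param seed Integer seed.
#' @param missing_prob Per-cell probability that the longitudinal value is
#'   missing.
#' @return A tibble with `participant_id`, `session_id` (the event), and
#'   `ab_p_demo__years`.
#' @examples
#' simulate_longitudinal(3, events = c("event_01", "event_02"), seed = 1)
#' @export
simulate_longitudinal <- function(n_participants,
                                  events = c("event_01", "event_02", "event_03"),
                                  seed = 1L, missing_prob = 0.2) {
  stopifnot(n_participants >= 1, length(events) >= 1)
  withr::with_seed(as.integer(seed), {
    grid <- expand.grid(
      session_id = events,
      participant_id = sprintf("sub%04d", seq_len(n_participants)),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid <- tibble::as_tibble(grid[c("participant_id", "session_id")])
    base <- rnorm(n_participants, 10, 2)
    drift <- match(grid$session_id, events) - 1
    value <- round(base[match(grid$participant_id, unique(grid$participant_id))] +
      drift + rnorm(nrow(grid), 0, 0.5), 1)
    value[runif(nrow(grid)) < missing_prob] <- NA
    grid$ab_p_demo__years <- value
    grid
  })
}
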