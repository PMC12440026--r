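# Naive single-row reference implementations of every kernel, written as
# plain loops/subsets so the vectorized kernels can be checked against an
# independent computation path.

oracle_nm <- function(v) sum(is.na(v))

oracle_gate <- function(v, max_na) {
  nm <- oracle_nm(v)
  nm <= max_na && nm < length(v)
}

oracle_mean <- function(v, max_na) {
  if (!oracle_gate(v, max_na)) {
    return(NA_real_)
  }
  mean(v[!is.na(v)])
}

oracle_sum <- function(v, max_na) {
  if (!oracle_gate(v, max_na)) {
    return(NA_real_)
  }
  sum(v[!is.na(v)])
}

oracle_prsum <- function(v, max_na) {
  if (!oracle_gate(v, max_na)) {
    return(NA_real_)
  }
  sum(v[!is.na(v)]) * length(v) / (length(v) - oracle_nm(v))
}

oracle_max <- function(v, max_na) {
  if (!oracle_gate(v, max_na)) {
    return(NA_real_)
  }
  max(v[!is.na(v)])
}

oracle_mean_pos <- function(v) {
  pos <- v[!is.na(v) & v > 0]
  if (length(pos) == 0) {
    return(NA_real_)
  }
  mean(pos)
}

oracle_count <- function(v, targets) {
  if (all(is.na(v))) {
    return(NA_integer_)
  }
  n <- 0L
  for (x in v) {
    if (!is.na(x) && x %in% targets) n <- n + 1L
  }
  n
}

oracle_count_cond <- function(row, conditions) {
  n <- 0L
  for (cond in conditions) {
    x <- row[[cond$column]]
    if (is.na(x)) {
      if (cond$missing_policy == "missing") {
        return(NA_integer_)
      }
      next
    }
    holds <- switch(cond$comparator,
      "==" = x == cond$reference,
      "!=" = x != cond$reference,
      "<" = x < cond$reference,
      "<=" = x <= cond$reference,
      ">" = x > cond$reference,
      ">=" = x >= cond$reference,
      "in" = x %in% cond$reference,
      "not-in" = !(x %in% cond$reference)
    )
    if (holds) n <- n + 1L
  }
  n
}

# Random item matrix with mixed missingness for property-style tests.
random_item_matrix <- function(n_rows, n_items, na_prob = 0.25) {
  m <- matrix(round(runif(n_rows * n_items, -3, 10), 2), nrow = n_rows)
  m[matrix(runif(n_rows * n_items) < na_prob, nrow = n_rows)] <- NA
  m
}

example_fes_definition <- function(max_na = 1) {
  score_definition(
    "fc_p_fes__cohes_mean",
    items = sprintf("fc_p_fes__cohes_%03d", 1:9),
    kernel = "ss_mean", max_na = max_na
  )
}
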