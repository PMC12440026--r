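test_that("kernels honor the missingness contract on single rows", {
  # ss_nm is always defined
  expect_identical(ss_nm(c(1, 2, 3)), 0L)
  expect_identical(ss_nm(rep(NA_real_, 9)), 9L)
  expect_identical(ss_nm(c(1, NA, 3, NA)), 2L)

  # ss_mean: nm <= max_na and at least one observed item
  expect_equal(ss_mean(c(2, 2, 2), max_na = 0), 2)
  expect_equal(ss_mean(c(1:7, NA, NA), max_na = 1), NA_real_)
  expect_equal(ss_mean(c(1:7, NA, NA), max_na = 2), 4)

  # ss_sum: as ss_mean, no proration
  expect_equal(ss_sum(c(1, 1, 1), max_na = 0), 3)
  expect_equal(ss_sum(c(1, NA, 3), max_na = 1), 4)
  expect_equal(ss_sum(c(NA, NA), max_na = 0), NA_real_)

  # ss_prsum: observed sum scaled by n/(n - nm)
  expect_equal(ss_prsum(c(2, 2, NA, 2), max_na = 1), 8)
  expect_equal(ss_prsum(c(3, NA, NA), max_na = 1), NA_real_)

  # ss_max
  expect_equal(ss_max(c(1, 7, 3), max_na = 0), 7)
  expect_equal(ss_max(c(NA, 2), max_na = 0), NA_real_)
  expect_equal(ss_max(c(NA, 2), max_na = 1), 2)

  # ss_mean_pos: only strictly positive observed values
  expect_equal(ss_mean_pos(c(1, 2, 3)), 2)
  expect_equal(ss_mean_pos(c(0, 2, 4)), 3)
  expect_equal(ss_mean_pos(c(0, 0, NA)), NA_real_)

  # ss_count: membership count; missing only when all items missing
  expect_identical(ss_count(c(1, 1, 0), target_levels = 1), 2L)
  expect_identical(ss_count(c(0, 0, 0), target_levels = 1), 0L)
  expect_identical(ss_count(rep(NA_real_, 3), target_levels = 1), NA_integer_)
})

test_that("all-missing rows stay missing even when max_na covers them", {
  v <- rep(NA_real_, 4)
  for (kernel in list(ss_mean, ss_sum, ss_prsum, ss_max)) {
    expect_true(is.na(kernel(v, max_na = 4)))
  }
})

test_that("max_na outside [0, n_items] is a parameter error", {
  expect_error(
    ss_mean(c(1, 2, 3), max_na = 4),
    class = "cohortscores_error_param"
  )
  expect_error(
    ss_sum(c(1, 2, 3), max_na = -1),
    class = "cohortscores_error_param"
  )
})

test_that("ss_count_cond counts satisfied row-level predicates", {
  row <- list(a = 5, b = 0)
  conds <- list(cond_spec("a", ">", 3), cond_spec("b", "==", 1))
  expect_identical(ss_count_cond(row, conds), 1L)
  expect_identical(ss_count_cond(row, list()), 0L)

  # a condition on a missing value is false by default ...
  expect_identical(
    ss_count_cond(list(a = NA), list(cond_spec("a", ">", 3))), 0L
  )
  # ... and propagates missingness under the "missing" policy
  expect_identical(
    ss_count_cond(
      list(a = NA),
      list(cond_spec("a", ">", 3, missing_policy = "missing"))
    ),
    NA_integer_
  )

  # set-valued comparators
  expect_identical(
    ss_count_cond(
      list(g = "b"),
      list(cond_spec("g", "in", c("a", "b")), cond_spec("g", "not-in", "b"))
    ),
    1L
  )

  expect_error(
    ss_count_cond(list(a = 1), list(cond_spec("zz", ">", 3))),
    "zz",
    class = "cohortscores_error_missing-column"
  )
  # comparator/reference arity must agree
  expect_error(cond_spec("a", ">", c(1, 2)), class = "cohortscores_error_param")
  expect_error(
    cond_spec("a", "in", numeric()),
    class = "cohortscores_error_param"
  )
})

test_that("ss_tscore is an exact stratified lookup", {
  global <- norm_table(data.frame(raw = c(5, 6), t = c(50, 53)))
  expect_equal(ss_tscore(5, global), 50)
  expect_equal(ss_tscore(NA_real_, global), NA_real_)
  expect_error(
    ss_tscore(99, global),
    "99",
    class = "cohortscores_error_param"
  )

  norms <- read_norm_table(
    system.file("extdata", "norms_synthetic.tsv", package = "cohortscores")
  )
  expect_equal(attr(norms, "stratum_cols"), "sex")
  expect_equal(ss_tscore(5, norms, stratum = list(sex = "f")), 50)
  expect_equal(ss_tscore(5, norms, stratum = list(sex = "m")), 52)
  # per-row strata
  expect_equal(
    ss_tscore(c(0, 10, NA), norms,
      stratum = data.frame(sex = c("f", "m", "f"))
    ),
    c(30, 72, NA)
  )
  expect_error(
    ss_tscore(5, norms, stratum = list(sex = "q")),
    "q",
    class = "cohortscores_error_param"
  )
  expect_error(ss_tscore(5, norms), class = "cohortscores_error_param")
  # duplicate (stratum, raw) entries are rejected at construction
  expect_error(
    norm_table(data.frame(raw = c(1, 1), t = c(40, 41))),
    class = "cohortscores_error_param"
  )
  expect_error(
    norm_table(data.frame(raw = 1, t = Inf)),
    class = "cohortscores_error_type"
  )
})

test_that("vectorized kernels equal the naive per-row oracle", {
  withr::local_seed(101)
  n_cases <- 0
  for (rep_i in 1:80) {
    n_items <- sample(1:20, 1)
    n_rows <- sample(1:15, 1)
    m <- random_item_matrix(n_rows, n_items)
    max_na <- sample(0:n_items, 1)
    targets <- sample(c(-1, 0, 1, 2), 2)

    expect_equal(ss_nm(m), apply(m, 1, oracle_nm))
    expect_equal(ss_mean(m, max_na), apply(m, 1, oracle_mean, max_na))
    expect_equal(ss_sum(m, max_na), apply(m, 1, oracle_sum, max_na))
    expect_equal(ss_prsum(m, max_na), apply(m, 1, oracle_prsum, max_na))
    expect_equal(ss_max(m, max_na), apply(m, 1, oracle_max, max_na))
    expect_equal(ss_mean_pos(m), apply(m, 1, oracle_mean_pos))
    expect_equal(
      ss_count(m, targets),
      apply(m, 1, oracle_count, targets)
    )
    n_cases <- n_cases + n_rows
  }
  expect_gte(n_cases, 500)
})

test_that("ss_count_cond equals the per-row oracle on random tables", {
  withr::local_seed(202)
  for (rep_i in 1:40) {
    n_rows <- sample(1:20, 1)
    d <- data.frame(
      a = sample(c(NA, 0:5), n_rows, replace = TRUE),
      b = sample(c(NA, -2:2), n_rows, replace = TRUE)
    )
    conds <- list(
      cond_spec("a", sample(c("<", "<=", ">", ">=", "==", "!="), 1), sample(0:5, 1)),
      cond_spec("b", "in", sample(-2:2, 2)),
      cond_spec("a", ">", 2,
        missing_policy = sample(c("false", "missing"), 1)
      )
    )
    got <- ss_count_cond(d, conds)
    want <- vapply(
      seq_len(n_rows),
      function(i) oracle_count_cond(as.list(d[i, ]), conds),
      integer(1)
    )
    expect_identical(got, want)
  }
})

test_that("kernel invariants hold on randomized inputs", {
  withr::local_seed(303)
  for (rep_i in 1:50) {
    n_items <- sample(2:20, 1)
    v <- random_item_matrix(1, n_items)[1, ]

    # conservation: nm + observed == n_items
    expect_identical(ss_nm(v) + sum(!is.na(v)), n_items)

    # missingness monotonicity: raising max_na never changes or loses a
    # computed value, it can only convert missing -> computed
    for (k in 0:(n_items - 1)) {
      for (kernel in list(ss_mean, ss_sum, ss_prsum, ss_max)) {
        at_k <- kernel(v, max_na = k)
        at_k1 <- kernel(v, max_na = k + 1)
        if (!is.na(at_k)) expect_identical(at_k1, at_k)
      }
    }

    # proration identity at zero missing
    full <- round(runif(n_items, -5, 5), 3)
    expect_identical(ss_prsum(full, max_na = 0), ss_sum(full, max_na = 0))

    # scale equivariance on fully observed vectors
    const <- sample(c(-2, 0.5, 3), 1)
    expect_equal(ss_mean(const * full, 0), const * ss_mean(full, 0))
    expect_equal(ss_sum(const * full, 0), const * ss_sum(full, 0))
  }
})
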