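fes_fixture <- function(n_rows = 6, seed = 7) {
  simulate_items(
    n_rows = n_rows, n_items = 9, levels = 0:1,
    pattern = missingness_pattern(per_row = c(0, 1, 2, 0, 1, 0), seed = seed),
    prefix = "fc_p_fes__cohes", seed = seed
  )
}

test_that("compute_score appends the score under its default name", {
  d <- fes_fixture()
  out <- compute_score(d, example_fes_definition(1))
  expect_equal(
    names(out),
    c(names(d), "fc_p_fes__cohes_mean", "fc_p_fes__cohes_nm")
  )
  expect_equal(nrow(out), nrow(d))
  expect_equal(out$participant_id, d$participant_id)
  # the nm companion records exactly the per-row missing counts
  expect_equal(out$fc_p_fes__cohes_nm, c(0L, 1L, 2L, 0L, 1L, 0L))
  # row with 2 missing exceeds max_na = 1
  expect_true(is.na(out$fc_p_fes__cohes_mean[3]))
  expect_false(anyNA(out$fc_p_fes__cohes_mean[-3]))
})

test_that("renaming the output changes the column name, not the values", {
  d <- fes_fixture()
  default_out <- compute_score(d, example_fes_definition(1))
  renamed <- compute_score(d, example_fes_definition(1), name = "my_score")
  expect_true(all(c("my_score", "my_score_nm") %in% names(renamed)))
  expect_equal(renamed$my_score, default_out$fc_p_fes__cohes_mean)
  expect_equal(renamed$my_score_nm, default_out$fc_p_fes__cohes_nm)
})

test_that("validation failures are informative classed errors", {
  d <- fes_fixture()
  # absent item columns: all of them listed
  d_missing <- d[setdiff(
    names(d), c("fc_p_fes__cohes_004", "fc_p_fes__cohes_007")
  )]
  err <- tryCatch(
    compute_score(d_missing, example_fes_definition(1)),
    condition = function(e) e
  )
  expect_s3_class(err, "cohortscores_error_missing-column")
  expect_match(conditionMessage(err), "fc_p_fes__cohes_004")
  expect_match(conditionMessage(err), "fc_p_fes__cohes_007")

  # wrong column type
  d_text <- d
  d_text$fc_p_fes__cohes_001 <- as.character(d_text$fc_p_fes__cohes_001)
  expect_error(
    compute_score(d_text, example_fes_definition(1)),
    "fc_p_fes__cohes_001",
    class = "cohortscores_error_type"
  )

  # parameter out of range echoes the bound
  expect_error(
    compute_score(d, example_fes_definition(1), max_na = 12),
    "max_na",
    class = "cohortscores_error_param"
  )

  # name collision with an existing column
  expect_error(
    compute_score(d, example_fes_definition(1), name = "fc_p_fes__cohes_001"),
    class = "cohortscores_error_name-collision"
  )
})

test_that("validate_input reports all violations without raising", {
  d <- fes_fixture()
  expect_equal(nrow(validate_input(d, example_fes_definition(1))), 0)

  d_bad <- d[setdiff(names(d), "fc_p_fes__cohes_002")]
  d_bad$fc_p_fes__cohes_003 <- "high"
  report <- validate_input(d_bad, example_fes_definition(1))
  expect_setequal(report$kind, c("missing-column", "type"))
  expect_equal(nrow(report), 2)
})

test_that("sentinel missing codes are recoded before the kernel runs", {
  d <- fes_fixture()
  d$fc_p_fes__cohes_001[1] <- 777
  d$fc_p_fes__cohes_002[1] <- 999
  out <- compute_score(
    d, example_fes_definition(1),
    missing_codes = c(777, 999)
  )
  expect_equal(out$fc_p_fes__cohes_nm[1], 2L)
  expect_true(is.na(out$fc_p_fes__cohes_mean[1]))
  # the raw input columns are returned untouched
  expect_equal(out$fc_p_fes__cohes_001[1], 777)
})

test_that("combine = FALSE output joins back to the combine = TRUE output", {
  d <- fes_fixture()
  combined <- compute_score(d, example_fes_definition(1), combine = TRUE)
  scores_only <- compute_score(d, example_fes_definition(1), combine = FALSE)
  expect_equal(
    names(scores_only),
    c(
      "participant_id", "session_id",
      "fc_p_fes__cohes_mean", "fc_p_fes__cohes_nm"
    )
  )
  joined <- dplyr::left_join(
    tibble::as_tibble(d), scores_only,
    by = c("participant_id", "session_id")
  )
  expect_equal(
    as.data.frame(joined), as.data.frame(combined),
    ignore_attr = TRUE
  )
})

test_that("identical inputs give identical outputs", {
  d <- fes_fixture()
  a <- compute_score(d, example_fes_definition(1))
  b <- compute_score(d, example_fes_definition(1))
  expect_identical(a, b)
})

test_that("compute_group equals the fold of compute_score over its members", {
  cat_obj <- read_catalog(example_catalog_path())
  bp <- simulate_bp(20, seed = 3, missing_prob = 0.15)
  grouped <- compute_group(bp, cat_obj, "ph_y_bp")

  acc <- tibble::as_tibble(bp)
  for (member in cat_obj$groups$ph_y_bp) {
    acc <- compute_score(
      acc, cat_obj$definitions[[member]],
      missing_codes = cat_obj$missing_codes, id_cols = cat_obj$id_columns
    )
  }
  expect_identical(grouped, acc)

  # nm companions sit immediately after their parent score
  new_cols <- setdiff(names(grouped), names(bp))
  expect_equal(
    new_cols,
    c(
      "ph_y_bp__sys_mean", "ph_y_bp__sys_nm",
      "ph_y_bp__dia_mean", "ph_y_bp__dia_nm",
      "ph_y_bp__hrate_mean", "ph_y_bp__hrate_nm"
    )
  )
})

test_that("unknown and empty groups are handled explicitly", {
  cat_obj <- read_catalog(example_catalog_path())
  bp <- simulate_bp(3, seed = 1)
  err <- tryCatch(
    compute_group(bp, cat_obj, "nope"),
    condition = function(e) e
  )
  expect_s3_class(err, "cohortscores_error_unknown-group")
  expect_match(conditionMessage(err), "ph_y_bp")

  empty_cat <- cat_obj
  empty_cat$groups$empty <- character()
  expect_warning(
    out <- compute_group(bp, empty_cat, "empty"),
    "empty"
  )
  expect_equal(names(out), names(bp))
})

test_that("tscore and count_cond definitions run through the engine", {
  norms <- read_norm_table(
    system.file("extdata", "norms_synthetic.tsv", package = "cohortscores")
  )
  d <- tibble::tibble(
    participant_id = c("p1", "p2", "p3"),
    session_id = "e1",
    sex = c("f", "m", "f"),
    mh_y_scale__tot_sum = c(0, 10, NA)
  )
  ts <- score_definition(
    "mh_y_scale__tot_tscore",
    items = "mh_y_scale__tot_sum", kernel = "ss_tscore",
    norms = norms, stratum_cols = "sex"
  )
  out <- compute_score(d, ts)
  expect_equal(out$mh_y_scale__tot_tscore, c(30, 72, NA))

  cc <- score_definition(
    "ph_y_scale__risk_count",
    items = "mh_y_scale__tot_sum", kernel = "ss_count_cond",
    conditions = list(
      cond_spec("mh_y_scale__tot_sum", ">=", 5),
      cond_spec("sex", "==", "f")
    ),
    nm_companion = FALSE
  )
  out_cc <- compute_score(d, cc)
  expect_equal(out_cc$ph_y_scale__risk_count, c(1L, 1L, 1L))
})

test_that("provenance records the definition and parameters used", {
  d <- fes_fixture()
  out <- compute_score(d, example_fes_definition(2))
  prov <- attr(out, "provenance")
  expect_named(
    prov, c("fc_p_fes__cohes_mean", "fc_p_fes__cohes_nm")
  )
  expect_equal(prov$fc_p_fes__cohes_mean$params$max_na, 2L)
  expect_equal(prov$fc_p_fes__cohes_mean$definition, "fc_p_fes__cohes_mean")
})
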