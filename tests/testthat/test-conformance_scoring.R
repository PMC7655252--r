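test_that("mandatory assessment counts missing items", {
  rules <- default_mandatory_rules()
  full <- assess_mandatory(make_perfect_record(), rules)
  expect_identical(full$X, 0L)
  expect_true(all(full$flags))

  empty <- assess_mandatory(make_empty_record(), rules)
  expect_identical(empty$X, 16L)
  expect_false(any(empty$flags))

  r <- make_perfect_record()
  r$age <- NA_integer_
  r$tcm_symptom_codes <- character(0)
  two <- assess_mandatory(r, rules)
  expect_identical(two$X, 2L)
  expect_false(two$flags[["age"]])
  expect_false(two$flags[["tcm_symptom_code"]])
})

test_that("coding assessment distinguishes strict and checked-if-present", {
  rules <- default_coding_rules()
  reg <- fixture_registry
  full <- assess_coding(make_perfect_record(), rules, reg)
  expect_identical(full$Y, 0L)

  r <- make_perfect_record()
  r$gender_code <- "1"
  expect_true(assess_coding(r, rules, reg)$flags[["gender_code"]])
  r$gender_code <- NA_character_  # strict: missing mandatory code counts
  expect_false(assess_coding(r, rules, reg)$flags[["gender_code"]])
  r$gender_code <- "7"            # out of range
  expect_false(assess_coding(r, rules, reg)$flags[["gender_code"]])

  # one invalid member spoils a list item
  r2 <- make_perfect_record()
  r2$syndrome_type_codes <- c("SYN-001", "ZZZ")
  expect_false(assess_coding(r2, rules, reg)$flags[["syndrome_code"]])

  # admin items are checked only when supplied
  r3 <- make_perfect_record()
  r3$admin_codes$ethnicity <- NA_character_
  expect_true(assess_coding(r3, rules, reg)$flags[["ethnicity_code"]])
  r3$admin_codes$ethnicity <- "96"
  expect_false(assess_coding(r3, rules, reg)$flags[["ethnicity_code"]])

  expect_error(assess_coding(make_perfect_record(), rules,
                             codeset_registry(list())),
               "does not resolve")
})

test_that("score formulas match their closed forms and reject n = 0", {
  expect_equal(integrity_score(c(0, 0, 0), k = 16), 100)
  expect_equal(integrity_score(c(1, 3), k = 4), 50)
  expect_equal(integrity_score(rep(16, 7), k = 16), 0)
  expect_equal(coding_score(c(0, 0), k = 13), 100)
  expect_equal(coding_score(c(13, 0), k = 13), 50)
  expect_equal(coding_score(c(1, 1, 1, 1), k = 2), 50)
  expect_error(integrity_score(numeric(0), k = 16), "empty batch")
  expect_error(coding_score(numeric(0), k = 13), "empty batch")
  expect_error(integrity_score(c(1, 17), k = 16), "in \\[0, k")
})

test_that("total score weighs the components and displays half-up", {
  expect_equal(total_score(75, 86), 80.5)
  expect_identical(display_score(total_score(75, 86)), 81L)
  expect_equal(total_score(100, 100), 100)
  expect_equal(total_score(0, 100), 50)
  expect_equal(total_score(0, 100, weights = c(0.7, 0.3)), 30)
  expect_error(total_score(50, 50, weights = c(0.6, 0.6)), "summing to 1")
  # half-up, not banker's rounding
  expect_identical(display_score(80.5), 81L)
  expect_identical(display_score(79.5), 80L)
  expect_identical(display_score(80.49), 80L)
})

test_that("batch scores agree with a brute-force record x rule recount", {
  cfg <- default_cfg
  set.seed(101)
  for (trial in 1:25) {
    n <- sample(1:50, 1)
    records <- lapply(seq_len(n), function(i) {
      make_random_record(paste0("R", i), runif(1, 0, 0.6), runif(1, 0, 0.5))
    })
    X <- vapply(records, function(r) {
      assess_mandatory(r, cfg$mandatory_rules)$X
    }, integer(1))
    Y <- vapply(records, function(r) {
      assess_coding(r, cfg$coding_rules, fixture_registry)$Y
    }, integer(1))
    X_oracle <- vapply(records, oracle_missing_count, integer(1),
                       rules = cfg$mandatory_rules)
    Y_oracle <- vapply(records, oracle_noncompliant_count, integer(1),
                       rules = cfg$coding_rules, registry = fixture_registry)
    expect_identical(X, X_oracle)
    expect_identical(Y, Y_oracle)
    expect_equal(integrity_score(X, 16),
                 (1 - sum(X_oracle) / (n * 16)) * 100)
    expect_equal(coding_score(Y, 13),
                 (1 - sum(Y_oracle) / (n * 13)) * 100)
  }
})

test_that("scores are bounded, permutation-invariant and monotone", {
  set.seed(202)
  for (trial in 1:50) {
    n <- sample(1:30, 1)
    X <- sample(0:16, n, replace = TRUE)
    Si <- integrity_score(X, 16)
    expect_gte(Si, 0)
    expect_lte(Si, 100)
    expect_equal(integrity_score(X[sample.int(length(X))], 16), Si)
    # filling in one missing item strictly increases the score
    i <- which(X > 0)[1]
    if (!is.na(i)) {
      X2 <- X
      X2[i] <- X2[i] - 1
      expect_gt(integrity_score(X2, 16), Si)
    }
    w <- runif(1)
    Sc <- coding_score(sample(0:13, n, replace = TRUE), 13)
    St <- total_score(Si, Sc, c(w, 1 - w))
    expect_gte(St, 0)
    expect_lte(St, 100)
  }
  # linearity of the default combination under scaling
  for (a in c(0, 0.25, 0.5, 1)) {
    expect_equal(total_score(a * 80, a * 60), a * total_score(80, 60))
  }
})
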