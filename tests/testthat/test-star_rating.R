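test_that("standards evaluate as pure conjunctions of rule flags", {
  scheme <- default_star_scheme()
  cfg <- default_cfg
  all_true <- list(
    mandatory_flags = stats::setNames(rep(TRUE, 16),
                                      names(cfg$mandatory_rules)),
    coding_flags = stats::setNames(rep(TRUE, 13), names(cfg$coding_rules)))
  expect_true(all(evaluate_standards(all_true, scheme)))

  all_false <- list(
    mandatory_flags = stats::setNames(rep(FALSE, 16),
                                      names(cfg$mandatory_rules)),
    coding_flags = stats::setNames(rep(FALSE, 13), names(cfg$coding_rules)))
  expect_false(any(evaluate_standards(all_false, scheme)))

  # flags satisfying exactly standards 1-7: blank the symptom item (std 8)
  # and everything after it
  partial <- all_true
  for (nm in c("tcm_symptom", "tcm_symptom_code", "tcm_diagnosis",
               "tcm_syndrome_type", "tcm_treatment")) {
    partial$mandatory_flags[[nm]] <- FALSE
  }
  b <- evaluate_standards(partial, scheme)
  expect_identical(unname(b[1:7]), rep(TRUE, 7))
  expect_false(any(b[8:12]))
  expect_identical(star_level(b, scheme), 2L)

  bad <- list(mandatory_flags = all_true$mandatory_flags,
              coding_flags = all_true$coding_flags)
  odd_scheme <- star_scheme(list(star_standard("s", mandatory = "ghost")),
                            thresholds = 1L)
  expect_error(evaluate_standards(bad, odd_scheme), "unknown mandatory rule")
})

test_that("star level is the largest fully-satisfied prefix", {
  scheme <- default_star_scheme()
  expect_identical(star_level(rep(TRUE, 14), scheme), 5L)
  expect_identical(star_level(rep(FALSE, 14), scheme), 0L)
  # standards 1-5 true, 6 false, rest arbitrary -> exactly 1 star
  b <- c(rep(TRUE, 5), FALSE, rep(TRUE, 8))
  expect_identical(star_level(b, scheme), 1L)
  # a false standard 3 forces 0 stars even if 4-14 all hold
  b2 <- rep(TRUE, 14)
  b2[3] <- FALSE
  expect_identical(star_level(b2, scheme), 0L)
  expect_error(star_level(rep(TRUE, 13), scheme), "14")
})

test_that("star level agrees with exhaustive prefix search", {
  scheme <- default_star_scheme()
  set.seed(303)
  for (i in 1:1000) {
    b <- runif(14) < runif(1)
    expect_identical(star_level(b, scheme),
                     oracle_star_level(b, scheme$thresholds))
  }
  # degenerate scheme: every one of the 2^5 flag vectors, level = leading
  # all-true run length
  d <- degenerate_scheme()
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  for (r in seq_len(nrow(grid))) {
    b <- as.logical(grid[r, ])
    run <- match(FALSE, b, nomatch = 6L) - 1L
    expect_identical(star_level(b, d), run)
    expect_identical(star_level(b, d), oracle_star_level(b, d$thresholds))
  }
})

test_that("star level is monotone in the standard flags", {
  scheme <- default_star_scheme()
  set.seed(404)
  for (i in 1:200) {
    b <- runif(14) < 0.6
    base <- star_level(b, scheme)
    j <- sample.int(14, 1)
    b2 <- b
    b2[j] <- TRUE
    expect_gte(star_level(b2, scheme), base)
    # prefix consistency at every level
    for (L in 1:5) {
      expect_identical(star_level(b, scheme) >= L,
                       all(b[seq_len(scheme$thresholds[L])]))
    }
  }
})

test_that("batch star is the count-weighted mean rounded half-up", {
  expect_identical(batch_star(c("5" = 10)), 5L)
  expect_identical(batch_star(c("0" = 3)), 0L)
  expect_identical(batch_star(c("2" = 1, "4" = 1)), 3L)
  expect_identical(batch_star(c("1" = 1, "2" = 1)), 2L)  # 1.5 rounds up
  expect_error(batch_star(c("0" = 0)), "positive total")
  expect_error(batch_star(stats::setNames(1, "x")), "integer")
})

test_that("scheme constructor validates thresholds", {
  s <- list(star_standard("a", mandatory = "m1"),
            star_standard("b", mandatory = "m2"))
  expect_error(star_scheme(s, thresholds = c(2, 1)), "strictly increasing")
  expect_error(star_scheme(s, thresholds = c(1, 3)), "must equal")
  expect_error(star_standard("empty"), "references no rule")
})
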