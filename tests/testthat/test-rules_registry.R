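test_that("default configuration carries 16 mandatory and 13 coding rules", {
  cfg <- default_rule_config()
  expect_length(cfg$mandatory_rules, 16)
  expect_length(cfg$coding_rules, 13)
  expect_equal(unname(cfg$weights), c(0.5, 0.5))
  # deterministic and stable across calls, ordering preserved
  expect_identical(cfg, default_rule_config())
  expect_identical(names(cfg$mandatory_rules)[1:3],
                   c("location", "pathological_nature", "four_diagnosis"))
  # strictness split: items also mandatory are strict, pure admin items not
  strict <- vapply(cfg$coding_rules, `[[`, logical(1), "strict")
  expect_identical(sum(strict), 6L)
  expect_false(strict[["ethnicity_code"]])
  expect_true(strict[["gender_code"]])
})

test_that("rule constructors reject requirement/field kind mismatches", {
  expect_error(mandatory_rule("x", "name", "AT_LEAST_ONE"), "list fields")
  expect_error(mandatory_rule("x", "tcm_symptoms", "NON_BLANK"), "scalar")
  expect_error(coding_rule("x", "not_a_field", "cs"), "does not resolve")
  expect_error(rule_config(weights = c(0.7, 0.4)), "summing to 1")
})

test_that("code sets normalize, deduplicate with a warning, reject empty", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,male", "2,female", "9,unknown"), f)
  cs <- load_codeset(f, "gender")
  expect_identical(cs$codes, c("1", "2", "9"))

  writeLines(c("1,male", "1,male again", "2,female"), f)
  expect_warning(cs2 <- load_codeset(f, "dup"), "duplicate")
  expect_identical(cs2$codes, c("1", "2"))

  writeLines(character(0), f)
  expect_error(load_codeset(f, "empty"), "empty")
})

test_that("fixture registry resolves every default coding rule", {
  reg <- fixture_codeset_registry()
  expect_true(validate_config(default_rule_config(), reg))
  ids <- vapply(default_coding_rules(), `[[`, character(1), "codeset_id")
  expect_setequal(ids, names(reg))
  expect_error(resolve_codeset(reg, "nonexistent_set"), "nonexistent_set")
})

test_that("configuration files override sections and fall back to defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("weights: {integrity: 0.7, coding: 0.3}", f)
  cfg <- load_rule_config(f)
  expect_equal(unname(cfg$weights), c(0.7, 0.3))
  expect_length(cfg$mandatory_rules, 16)
  expect_length(cfg$coding_rules, 13)

  # empty file = full fallback to the defaults
  writeLines("", f)
  expect_identical(load_rule_config(f), default_rule_config())

  # schema violations name the offending key
  writeLines("wieghts: {integrity: 1}", f)
  expect_error(load_rule_config(f), "wieghts")
  writeLines(c("coding_rules:",
               "  - {item: a, field: gender_code, codeset: X}",
               "star_scheme:",
               "  thresholds: [1]",
               "  standards:",
               "    - {name: s1, mandatory: [name]}"), f)
  cfg_x <- load_rule_config(f)
  expect_error(validate_config(cfg_x, fixture_codeset_registry()), "X")
  writeLines("weights: {integrity: 0.9, coding: 0.3}", f)
  expect_error(load_rule_config(f), "summing to 1")
})

test_that("a full custom configuration document round-trips", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "weights: {integrity: 0.6, coding: 0.4}",
    "mandatory_rules:",
    "  - {item: name, field: name, requirement: NON_BLANK}",
    "  - {item: symptoms, field: tcm_symptoms, requirement: AT_LEAST_ONE}",
    "coding_rules:",
    "  - {item: gender, field: gender_code, codeset: ws445_gender,",
    "     strict: true}",
    "star_scheme:",
    "  thresholds: [1, 2]",
    "  standards:",
    "    - {name: named, mandatory: [name]}",
    "    - {name: gender_valid, coding: [gender]}"), f)
  cfg <- load_rule_config(f)
  expect_length(cfg$mandatory_rules, 2)
  expect_length(cfg$coding_rules, 1)
  expect_identical(cfg$star_scheme$thresholds, c(1L, 2L))
  r <- assess_record(make_perfect_record(), cfg, fixture_codeset_registry())
  expect_identical(r$star, 2L)
})

test_that("schemes referencing unknown rules are rejected", {
  bad <- star_scheme(list(star_standard("s1", mandatory = "no_such_rule")),
                     thresholds = 1L)
  expect_error(rule_config(star_scheme = bad), "no_such_rule")
})
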