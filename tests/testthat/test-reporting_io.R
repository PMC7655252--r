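test_that("record files read back row-for-row with warnings, never drops", {
  recs <- list(make_perfect_record("A"), make_empty_record("B"),
               make_random_record("C", 0.3, 0.3))
  for (fmt in c("csv", "jsonl")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_records(recs, f, fmt)
    rr <- read_records(f, fmt)
    expect_length(rr$records, 3)
    expect_length(rr$warnings, 0)
    expect_identical(lapply(rr$records, unclass), lapply(recs, unclass))
  }

  # malformed age among good rows: record kept with field missing, 1 warning
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,name,age", "R1,Li,40", "R2,Wang,-3", "R3,Zhao,12"),
             f)
  rr <- read_records(f, "csv")
  expect_length(rr$records, 3)
  expect_length(rr$warnings, 1)
  expect_match(rr$warnings, "row 2")
  expect_true(is.na(rr$records[[2]]$age))

  # duplicate ids: both kept, warned
  writeLines(c("record_id,name", "R1,Li", "R1,Wang"), f)
  rr2 <- read_records(f, "csv")
  expect_length(rr2$records, 2)
  expect_match(rr2$warnings, "duplicate")

  # empty file: zero records, scoring then refuses the batch
  writeLines(character(0), f)
  rr3 <- read_records(f, "csv")
  expect_length(rr3$records, 0)
  expect_error(assess_batch(rr3$records), "n = 0")
  expect_error(read_records(tempfile(), "csv"), "not found")
})

test_that("batch assessment composes scores, stars and detail", {
  rep <- assess_batch(list(make_perfect_record("A"), make_perfect_record("B")),
                      institution = "Test Hospital")
  expect_identical(rep$n, 2L)
  expect_equal(rep$scores$Si, 100)
  expect_equal(rep$scores$Sc, 100)
  expect_equal(rep$scores$St, 100)
  expect_equal(unname(rep$star_counts[["5"]]), 2)
  expect_identical(rep$batch_star, 5L)
  expect_identical(sum(rep$star_counts), 2)
  expect_identical(nrow(rep$detail), 2L)

  rep0 <- assess_batch(list(make_empty_record()))
  expect_equal(rep0$scores$Si, 0)
  expect_identical(unname(rep0$detail$star), 0L)
  # every mandatory item is listed as failed
  expect_true(grepl("name", rep0$detail$failed_items))
})

test_that("reports round-trip losslessly through JSON", {
  b <- generate_batch(batch_spec(c("0" = 3, "2" = 4, "5" = 3), seed = 5))
  rep <- assess_batch(b$records, warnings = "row 9: synthetic warning")
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f, "json")
  back <- read_report(f)
  expect_identical(back$n, rep$n)
  expect_identical(back$scores$Si, rep$scores$Si)
  expect_identical(back$scores$St_display, rep$scores$St_display)
  expect_identical(back$star_counts, rep$star_counts)
  expect_identical(back$batch_star, rep$batch_star)
  expect_identical(back$detail, rep$detail)
  expect_identical(back$warnings, rep$warnings)
  expect_identical(back$metadata$config_fingerprint,
                   rep$metadata$config_fingerprint)
})

test_that("JSON output is deterministic modulo the timestamp", {
  b <- generate_batch(batch_spec(c("1" = 3, "4" = 2), seed = 8))
  r1 <- assess_batch(b$records)
  r2 <- assess_batch(b$records)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  r1$metadata$timestamp <- r2$metadata$timestamp <- "1970-01-01T00:00:00Z"
  write_report(r1, f1, "json")
  write_report(r2, f2, "json")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("markdown report shows half-up displayed scores, stars 5 to 0", {
  recs <- list(make_perfect_record("A"), make_empty_record("B"))
  rep <- assess_batch(recs)
  # Si = Sc = 50, St = 50; force the worked half-point display instead
  rep$scores$St <- 80.5
  rep$scores$St_display <- display_score(80.5)
  f <- withr::local_tempfile(fileext = ".md")
  write_report(rep, f, "markdown")
  md <- readLines(f)
  expect_true(any(grepl("\\*\\*81\\*\\*", md)))
  star_rows <- grep("-star \\|", md, value = TRUE)
  expect_identical(substr(star_rows, 3, 3), as.character(5:0))
})
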