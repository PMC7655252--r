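# Shared fixtures and independent oracles for the test suite.

fixture_registry <- fixture_codeset_registry()
default_cfg <- default_rule_config()

# A record satisfying every default rule (valid fixture codes everywhere).
make_perfect_record <- function(id = "R1") {
  outpatient_record(
    record_id = id,
    location = "Clinic A",
    pathological_nature = "deficiency",
    four_diagnosis = c("pale tongue", "wiry pulse"),
    tcm_symptoms = c("fatigue", "dizziness"),
    tcm_symptom_codes = c("DIS-001", "DIS-002"),
    tcm_diagnosis = "qi deficiency disorder",
    syndrome_types = "qi deficiency",
    syndrome_type_codes = "SYN-001",
    treatments = "tonify qi",
    treatment_codes = "TM-001",
    name = "Zhang San",
    id_number = "SYN000000001",
    age = 42,
    gender_code = "1",
    dominant_disease_flag = "Y",
    dominant_disease_codes = "DD01",
    admin_codes = list(ethnicity = "01", medical_insurance_type = "1",
                       disease_severity = "2", id_type = "01",
                       diagnosis_type = "1", payment_method = "01",
                       nationality = "CHN"))
}

# A record with every assessable item missing.
make_empty_record <- function(id = "R0") {
  outpatient_record(record_id = id)
}

# Cheap random record: each mandatory item independently blanked, each code
# independently drawn valid or out-of-range. Used to exercise scoring paths
# without the ground-truth generator.
make_random_record <- function(id, p_missing = 0.3, p_invalid = 0.2) {
  pick_code <- function(codeset_id) {
    if (runif(1) < p_invalid) "BAD-CODE" else
      sample(fixture_registry[[codeset_id]]$codes, 1L)
  }
  maybe <- function(x) if (runif(1) < p_missing) NA else x
  maybe_list <- function(x) if (runif(1) < p_missing) character(0) else x
  outpatient_record(
    record_id = id,
    location = maybe("Clinic A"),
    pathological_nature = maybe("excess"),
    four_diagnosis = maybe_list("wiry pulse"),
    tcm_symptoms = maybe_list(c("fatigue", "cough")),
    tcm_symptom_codes = maybe_list(pick_code("gbt_diseases")),
    tcm_diagnosis = maybe("stagnation disorder"),
    syndrome_types = maybe_list("blood stasis"),
    syndrome_type_codes = maybe_list(pick_code("gbt_syndromes")),
    treatments = maybe_list("invigorate blood"),
    treatment_codes = maybe_list(pick_code("gbt_therapeutic_methods")),
    name = maybe("Li Si"),
    id_number = maybe("SYN000000002"),
    age = maybe(33),
    gender_code = maybe(pick_code("ws445_gender")),
    dominant_disease_flag = maybe("N"),
    dominant_disease_codes = maybe_list("DD02"),
    admin_codes = list(ethnicity = maybe(pick_code("ws445_ethnicity")),
                       payment_method = maybe(pick_code("ws445_payment_method"))))
}

# ---- independent oracles ---------------------------------------------------

# Brute-force recount of missing mandatory items: inspects raw record fields
# directly, one record x rule pair at a time.
oracle_missing_count <- function(record, rules) {
  miss <- 0L
  for (rule in rules) {
    p <- rule$field_path
    val <- if (grepl("^admin_codes\\.", p)) {
      record$admin_codes[[sub("^admin_codes\\.", "", p)]]
    } else record[[p]]
    absent <- if (rule$requirement == "AT_LEAST_ONE") {
      length(val) == 0L
    } else {
      is.null(val) || is.na(val)
    }
    if (absent) miss <- miss + 1L
  }
  miss
}

# Brute-force recount of noncompliant coding items.
oracle_noncompliant_count <- function(record, rules, registry) {
  bad <- 0L
  for (rule in rules) {
    p <- rule$field_path
    val <- if (grepl("^admin_codes\\.", p)) {
      record$admin_codes[[sub("^admin_codes\\.", "", p)]]
    } else record[[p]]
    codes <- val[!is.na(val)]
    valid <- registry[[rule$codeset_id]]$codes
    noncompliant <- if (length(codes) == 0L) {
      rule$strict
    } else {
      any(!codes %in% valid)
    }
    if (noncompliant) bad <- bad + 1L
  }
  bad
}

# Exhaustive prefix search for the star level: highest level whose full
# threshold prefix holds, scanning from the top.
oracle_star_level <- function(bools, thresholds) {
  for (L in rev(seq_along(thresholds))) {
    if (all(bools[seq_len(thresholds[L])])) return(L)
  }
  0L
}

# Degenerate 5-standard scheme with thresholds 1..5: star level must equal
# the length of the leading all-true run.
degenerate_scheme <- function() {
  star_scheme(
    standards = lapply(1:5, function(i) {
      star_standard(paste0("s", i), mandatory = "name")
    }),
    thresholds = 1:5)
}

expect_same_flags <- function(a, b) {
  expect_identical(a$mandatory_flags, b$mandatory_flags)
  expect_identical(a$coding_flags, b$coding_flags)
  expect_identical(a$X, b$X)
  expect_identical(a$Y, b$Y)
  expect_identical(a$star, b$star)
}
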