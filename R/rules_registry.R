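# Rule registry: default mandatory-item and coding rules, the default star
# scheme, code-set loading, and rule-configuration files.

#' Mandatory-item rule
#'
#' One completeness requirement: a scalar field that cannot be blank
#' (`NON_BLANK`) or a multi-valued field that needs at least one entry
#' (`AT_LEAST_ONE`).
#'
#' @param item_name Rule label (unique within a configuration).
#' @param field_path Record field the rule inspects.
#' @param requirement `"NON_BLANK"` (scalar fields) or `"AT_LEAST_ONE"`
#'   (list fields).
#' @return A `mandatory_rule` object.
#' @export
mandatory_rule <- function(item_name, field_path,
                           requirement = c("NON_BLANK", "AT_LEAST_ONE")) {
  requirement <- match.arg(requirement)
  kind <- field_kind(field_path)
  if (requirement == "NON_BLANK" && kind != "scalar") {
    stop("NON_BLANK applies only to scalar fields; ", sQuote(field_path),
         " is a list field", call. = FALSE)
  }
  if (requirement == "AT_LEAST_ONE" && kind != "list") {
    stop("AT_LEAST_ONE applies only to list fields; ", sQuote(field_path),
         " is a scalar field", call. = FALSE)
  }
  structure(list(item_name = item_name, field_path = field_path,
                 requirement = requirement),
            class = "mandatory_rule")
}

#' Coding rule
#'
#' One code-range requirement: every code present in `field_path` must be a
#' member of the named code set. `strict` rules (items that are also
#' mandatory) are additionally noncompliant when no code is present at all;
#' non-strict rules are checked only if a value was supplied.
#'
#' @param item_name Rule label.
#' @param field_path Code-bearing record field (scalar or list).
#' @param codeset_id Identifier resolved against a [codeset_registry()].
#' @param standard_source Free-text provenance label for the code standard.
#' @param strict Logical; if `TRUE` a missing code is noncompliant.
#' @return A `coding_rule` object.
#' @export
coding_rule <- function(item_name, field_path, codeset_id,
                        standard_source = "", strict = TRUE) {
  field_kind(field_path)  # validates the path
  structure(list(item_name = item_name, field_path = field_path,
                 codeset_id = codeset_id, standard_source = standard_source,
                 strict = isTRUE(strict)),
            class = "coding_rule")
}

#' Code set: the valid code range for one coded item
#'
#' Membership is exact string equality on normalized codes (case-sensitive;
#' code systems are case-defined).
#'
#' @param codeset_id Identifier.
#' @param codes Character vector of valid codes (non-empty after
#'   normalization; duplicates collapsed with a warning).
#' @param terms Optional display terms, parallel to `codes`.
#' @param source_label Provenance of the code range.
#' @return A `codeset` object.
#' @export
codeset <- function(codeset_id, codes, terms = NULL, source_label = "") {
  codes <- normalize_values(codes)
  if (length(codes) == 0L) {
    stop("code set ", sQuote(codeset_id), " is empty: a code range cannot ",
         "be empty", call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    warning("code set ", sQuote(codeset_id),
            " contains duplicate codes; collapsing", call. = FALSE)
    keep <- !duplicated(codes)
    if (!is.null(terms)) terms <- terms[keep]
    codes <- codes[keep]
  }
  if (!is.null(terms)) {
    terms <- vapply(as.character(terms), normalize_value, character(1L),
                    USE.NAMES = FALSE)
    stopifnot(length(terms) == length(codes))
  }
  structure(list(codeset_id = codeset_id, codes = codes, terms = terms,
                 source_label = source_label),
            class = "codeset")
}

#' Load a code set from a two-column delimited file
#'
#' Expects UTF-8 rows of `code<sep>term`. The separator defaults on the file
#' extension (`.tsv` = tab, otherwise comma). An empty file is an error: a
#' code range cannot be empty.
#'
#' @param path File path.
#' @param codeset_id Identifier for the loaded set (default: file base name).
#' @param sep Column separator; `NULL` picks by extension.
#' @param header Logical; skip a header row.
#' @param source_label Provenance label.
#' @return A [codeset()].
#' @export
load_codeset <- function(path, codeset_id = NULL, sep = NULL,
                         header = FALSE, source_label = "") {
  if (!file.exists(path)) stop("code set file not found: ", path, call. = FALSE)
  if (is.null(codeset_id)) {
    codeset_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = header, quote = "\"",
                      colClasses = "character", fill = TRUE,
                      fileEncoding = "UTF-8", comment.char = ""),
    error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) {
    stop("code set file ", sQuote(path), " is empty: a code range cannot ",
         "be empty", call. = FALSE)
  }
  codeset(codeset_id, codes = tab[[1L]],
          terms = if (ncol(tab) >= 2L) tab[[2L]] else NULL,
          source_label = source_label)
}

#' Code-set registry
#'
#' @param codesets List of [codeset()] objects.
#' @return A `codeset_registry` mapping codeset_id to code set.
#' @export
codeset_registry <- function(codesets = list()) {
  stopifnot(all(vapply(codesets, inherits, logical(1L), "codeset")))
  ids <- vapply(codesets, `[[`, character(1L), "codeset_id")
  if (anyDuplicated(ids)) {
    stop("duplicate codeset_id in registry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(codesets, ids), class = "codeset_registry")
}

resolve_codeset <- function(registry, codeset_id) {
  if (!inherits(registry, "codeset_registry")) {
    stop("registry must be a codeset_registry", call. = FALSE)
  }
  cs <- registry[[codeset_id]]
  if (is.null(cs)) {
    stop("code set ", sQuote(codeset_id),
         " does not resolve in the registry", call. = FALSE)
  }
  cs
}

#' Load every code set in a directory
#'
#' Loads all `.tsv`/`.csv` files in `dir` as code sets keyed by file base
#' name.
#'
#' @param dir Directory of two-column code files.
#' @inheritParams load_codeset
#' @return A [codeset_registry()].
#' @export
load_codeset_dir <- function(dir, header = FALSE) {
  files <- list.files(dir, pattern = "\\.(tsv|csv)$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no .tsv/.csv code set files found in ", dir, call. = FALSE)
  }
  codeset_registry(lapply(files, load_codeset, header = header))
}

#' Fixture code sets for testing
#'
#' Returns a registry of small *synthetic* code sets shipped with the
#' package, one per default coding rule. These are invented fixtures: the
#' package does not redistribute the content of WS 445.11-2014 or the GB/T
#' clinical terminology standards, whose real code tables users must load at
#' runtime with [load_codeset_dir()].
#'
#' @return A [codeset_registry()] with the 13 fixture sets.
#' @export
fixture_codeset_registry <- function() {
  dir <- system.file("extdata", "fixture_codesets", package = "emrqc")
  load_codeset_dir(dir)
}

.WS445 <- "WS 445.11-2014 (fixture code range)"
.GBT <- "GB/T clinical terminology (fixture code range)"

#' Default mandatory-item rules
#'
#' The 16 default completeness rules, in order: location, pathological
#' nature, four-diagnosis findings, TCM symptom code, TCM symptom, TCM
#' diagnosis, syndrome type, syndrome type code, treatment, treatment code,
#' name, ID number, age, gender code, dominant-disease identification and
#' dominant-disease code.
#'
#' @return Ordered list of [mandatory_rule()] objects.
#' @export
default_mandatory_rules <- function() {
  list(
    mandatory_rule("location", "location", "NON_BLANK"),
    mandatory_rule("pathological_nature", "pathological_nature", "NON_BLANK"),
    mandatory_rule("four_diagnosis", "four_diagnosis", "AT_LEAST_ONE"),
    mandatory_rule("tcm_symptom_code", "tcm_symptom_codes", "AT_LEAST_ONE"),
    mandatory_rule("tcm_symptom", "tcm_symptoms", "AT_LEAST_ONE"),
    mandatory_rule("tcm_diagnosis", "tcm_diagnosis", "NON_BLANK"),
    mandatory_rule("tcm_syndrome_type", "syndrome_types", "AT_LEAST_ONE"),
    mandatory_rule("tcm_syndrome_type_code", "syndrome_type_codes",
                   "AT_LEAST_ONE"),
    mandatory_rule("tcm_treatment", "treatments", "AT_LEAST_ONE"),
    mandatory_rule("tcm_treatment_code", "treatment_codes", "AT_LEAST_ONE"),
    mandatory_rule("name", "name", "NON_BLANK"),
    mandatory_rule("id_number", "id_number", "NON_BLANK"),
    mandatory_rule("age", "age", "NON_BLANK"),
    mandatory_rule("gender_code", "gender_code", "NON_BLANK"),
    mandatory_rule("dominant_disease_flag", "dominant_disease_flag",
                   "NON_BLANK"),
    mandatory_rule("dominant_disease_code", "dominant_disease_codes",
                   "AT_LEAST_ONE")
  )
}

#' Default coding rules
#'
#' The 13 default code-range rules: nine administrative items whose value
#' sets come from the health-industry standard WS 445.11-2014, and four TCM
#' terminology items (therapeutic methods, syndromes, diseases, and the
#' classification-and-codes of diseases and Zheng) from national terminology
#' standards. Rules whose item is also mandatory are strict (a missing code
#' is noncompliant); purely administrative items are checked only when a
#' value is supplied.
#'
#' @return Ordered list of [coding_rule()] objects.
#' @export
default_coding_rules <- function() {
  list(
    coding_rule("ethnicity_code", "admin_codes.ethnicity",
                "ws445_ethnicity", .WS445, strict = FALSE),
    coding_rule("medical_insurance_code", "admin_codes.medical_insurance_type",
                "ws445_medical_insurance", .WS445, strict = FALSE),
    coding_rule("disease_severity_code", "admin_codes.disease_severity",
                "ws445_disease_severity", .WS445, strict = FALSE),
    coding_rule("gender_code", "gender_code",
                "ws445_gender", .WS445, strict = TRUE),
    coding_rule("id_type_code", "admin_codes.id_type",
                "ws445_id_type", .WS445, strict = FALSE),
    coding_rule("dominant_disease_code", "dominant_disease_codes",
                "ws445_dominant_disease", .WS445, strict = TRUE),
    coding_rule("diagnosis_type_code", "admin_codes.diagnosis_type",
                "ws445_diagnosis_type", .WS445, strict = FALSE),
    coding_rule("payment_method_code", "admin_codes.payment_method",
                "ws445_payment_method", .WS445, strict = FALSE),
    coding_rule("nationality_code", "admin_codes.nationality",
                "ws445_nationality", .WS445, strict = FALSE),
    coding_rule("therapeutic_method_code", "treatment_codes",
                "gbt_therapeutic_methods", .GBT, strict = TRUE),
    coding_rule("syndrome_code", "syndrome_type_codes",
                "gbt_syndromes", .GBT, strict = TRUE),
    coding_rule("disease_code", "tcm_symptom_codes",
                "gbt_diseases", .GBT, strict = TRUE),
    coding_rule("disease_zheng_code", "dominant_disease_codes",
                "gbt_disease_zheng", .GBT, strict = TRUE)
  )
}

#' Rule configuration
#'
#' Bundles the ordered mandatory rules, ordered coding rules, star scheme and
#' score weights that drive a whole assessment. `k_integrity` and `k_coding`
#' (the denominators of the integrity and coding scores) are the rule counts.
#'
#' @param mandatory_rules Ordered list of [mandatory_rule()] (>= 1).
#' @param coding_rules Ordered list of [coding_rule()] (>= 1).
#' @param star_scheme A [star_scheme()].
#' @param weights Length-2 numeric `(w_integrity, w_coding)` summing to 1.
#' @return A `rule_config` object.
#' @export
rule_config <- function(mandatory_rules = default_mandatory_rules(),
                        coding_rules = default_coding_rules(),
                        star_scheme = default_star_scheme(),
                        weights = c(integrity = 0.5, coding = 0.5)) {
  stopifnot(length(mandatory_rules) >= 1L, length(coding_rules) >= 1L)
  stopifnot(all(vapply(mandatory_rules, inherits, logical(1L),
                       "mandatory_rule")))
  stopifnot(all(vapply(coding_rules, inherits, logical(1L), "coding_rule")))
  weights <- as.numeric(weights)
  if (length(weights) != 2L || anyNA(weights) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be two non-negative numbers summing to 1",
         call. = FALSE)
  }
  mnames <- vapply(mandatory_rules, `[[`, character(1L), "item_name")
  cnames <- vapply(coding_rules, `[[`, character(1L), "item_name")
  if (anyDuplicated(mnames) || anyDuplicated(cnames)) {
    stop("rule item names must be unique within each rule list",
         call. = FALSE)
  }
  cfg <- structure(
    list(mandatory_rules = stats::setNames(mandatory_rules, mnames),
         coding_rules = stats::setNames(coding_rules, cnames),
         star_scheme = star_scheme,
         weights = c(integrity = weights[1L], coding = weights[2L])),
    class = "rule_config")
  validate_scheme_references(star_scheme, cfg)
  cfg
}

#' Default rule configuration
#'
#' The stock configuration: 16 mandatory rules, 13 coding rules, equal
#' integrity/coding weights (0.5, 0.5) and the default cumulative 14-standard
#' star scheme. Deterministic and stable across calls.
#'
#' @return A [rule_config()] with `k_integrity = 16` and `k_coding = 13`.
#' @export
default_rule_config <- function() rule_config()

k_integrity <- function(config) length(config$mandatory_rules)
k_coding <- function(config) length(config$coding_rules)

#' @export
print.rule_config <- function(x, ...) {
  cat("<rule_config>\n")
  cat("  mandatory rules (k_integrity):", k_integrity(x), "\n")
  cat("  coding rules   (k_coding):   ", k_coding(x), "\n")
  cat("  weights: integrity", x$weights[["integrity"]],
      "/ coding", x$weights[["coding"]], "\n")
  cat("  star scheme:", length(x$star_scheme$standards), "standards,",
      "thresholds", paste(x$star_scheme$thresholds, collapse = "/"), "\n")
  invisible(x)
}

#' Validate that a configuration's code sets resolve
#'
#' @param config A [rule_config()].
#' @param registry A [codeset_registry()].
#' @return Invisibly `TRUE`; errors naming the first unresolved codeset_id.
#' @export
validate_config <- function(config, registry) {
  stopifnot(inherits(config, "rule_config"))
  for (rule in config$coding_rules) resolve_codeset(registry, rule$codeset_id)
  invisible(TRUE)
}

#' Load a rule configuration from YAML or JSON
#'
#' Sections omitted from the file fall back to the defaults, so an empty file
#' yields [default_rule_config()]. The schema:
#'
#' ```yaml
#' weights: {integrity: 0.5, coding: 0.5}
#' mandatory_rules:
#'   - {item: location, field: location, requirement: NON_BLANK}
#' coding_rules:
#'   - {item: gender_code, field: gender_code, codeset: ws445_gender,
#'      source: "WS 445.11-2014", strict: true}
#' star_scheme:
#'   thresholds: [5, 7, 9, 11, 14]
#'   standards:
#'     - {name: patient_name, mandatory: [name]}
#'     - {name: symptom_code_valid, mandatory: [tcm_symptom_code],
#'        coding: [disease_code]}
#' ```
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A [rule_config()].
#' @export
load_rule_config <- function(path) {
  if (!file.exists(path)) {
    stop("rule configuration file not found: ", path, call. = FALSE)
  }
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) {
    stop("rule configuration must be a mapping at top level", call. = FALSE)
  }
  known <- c("weights", "mandatory_rules", "coding_rules", "star_scheme")
  bad <- setdiff(names(doc), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  weights <- c(integrity = 0.5, coding = 0.5)
  if (!is.null(doc$weights)) {
    w <- doc$weights
    if (is.null(w$integrity) || is.null(w$coding)) {
      stop("configuration key 'weights' needs 'integrity' and 'coding'",
           call. = FALSE)
    }
    weights <- c(integrity = as.numeric(w$integrity),
                 coding = as.numeric(w$coding))
  }
  mand <- if (is.null(doc$mandatory_rules)) default_mandatory_rules() else {
    lapply(doc$mandatory_rules, function(r) {
      need_keys(r, c("item", "field", "requirement"), "mandatory_rules")
      mandatory_rule(r$item, r$field, r$requirement)
    })
  }
  cod <- if (is.null(doc$coding_rules)) default_coding_rules() else {
    lapply(doc$coding_rules, function(r) {
      need_keys(r, c("item", "field", "codeset"), "coding_rules")
      coding_rule(r$item, r$field, r$codeset,
                  standard_source = r$source %||% "",
                  strict = r$strict %||% TRUE)
    })
  }
  scheme <- if (is.null(doc$star_scheme)) default_star_scheme() else {
    s <- doc$star_scheme
    need_keys(s, c("thresholds", "standards"), "star_scheme")
    star_scheme(
      standards = lapply(s$standards, function(st) {
        need_keys(st, "name", "star_scheme$standards")
        star_standard(st$name,
                      mandatory = as.character(unlist(st$mandatory)),
                      coding = as.character(unlist(st$coding)))
      }),
      thresholds = as.integer(unlist(s$thresholds)))
  }
  rule_config(mand, cod, scheme, weights)
}

need_keys <- function(x, keys, where) {
  miss <- setdiff(keys, names(x))
  if (length(miss)) {
    stop("configuration section ", sQuote(where), " is missing key(s): ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
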