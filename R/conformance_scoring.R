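# Conformance scoring: per-record missing / noncompliant counts and the
# batch-level integrity, coding and total scores.
#
#   Si = (1 - sum(X_i) / (n * k_integrity)) * 100
#   Sc = (1 - sum(Y_i) / (n * k_coding))    * 100
#   St = w1 * Si + w2 * Sc        (default weights 0.5 / 0.5)
#
# Scores are carried at full precision; rounding (half-up to whole points)
# happens only at display time.

#' Assess the mandatory items of one record
#'
#' A rule is satisfied when its `NON_BLANK` scalar is non-missing, or its
#' `AT_LEAST_ONE` list is non-empty. `X` is the number of unsatisfied
#' (missing) mandatory items.
#'
#' @param record An [outpatient_record()].
#' @param rules Ordered list of [mandatory_rule()] (non-empty).
#' @return List with `X` (integer missing count) and `flags` (named ordered
#'   logical vector, `TRUE` = satisfied).
#' @export
assess_mandatory <- function(record, rules) {
  stopifnot(inherits(record, "outpatient_record"), length(rules) >= 1L)
  flags <- vapply(rules, function(rule) {
    val <- get_field(record, rule$field_path)
    if (rule$requirement == "AT_LEAST_ONE") length(val) > 0L else !is.na(val)
  }, logical(1L))
  names(flags) <- vapply(rules, `[[`, character(1L), "item_name")
  list(X = sum(!flags), flags = flags)
}

#' Assess the coded items of one record
#'
#' A coding item is compliant when every code present in its field is a
#' member of the bound code set; one out-of-range code spoils the item. For
#' strict rules an item with no code at all is also noncompliant; non-strict
#' rules treat an absent value as compliant (checked only if present). `Y`
#' is the number of noncompliant coding items.
#'
#' @param record An [outpatient_record()].
#' @param rules Ordered list of [coding_rule()] (non-empty).
#' @param registry A [codeset_registry()] resolving every rule's codeset_id.
#' @return List with `Y` (integer noncompliant count) and `flags` (named
#'   ordered logical vector, `TRUE` = compliant).
#' @export
assess_coding <- function(record, rules, registry) {
  stopifnot(inherits(record, "outpatient_record"), length(rules) >= 1L)
  flags <- vapply(rules, function(rule) {
    cs <- resolve_codeset(registry, rule$codeset_id)
    codes <- field_codes(record, rule$field_path)
    if (length(codes) == 0L) return(!rule$strict)
    all(codes %in% cs$codes)
  }, logical(1L))
  names(flags) <- vapply(rules, `[[`, character(1L), "item_name")
  list(Y = sum(!flags), flags = flags)
}

# Codes present in a field, as a character vector (empty when missing).
field_codes <- function(record, path) {
  val <- get_field(record, path)
  if (field_kind(path) == "list") return(val)
  if (is.na(val)) character(0) else as.character(val)
}

#' Assess one record against a full configuration
#'
#' Runs the mandatory and coding assessments and rates the record on the
#' configuration's star scheme.
#'
#' @param record An [outpatient_record()].
#' @param config A [rule_config()].
#' @param registry A [codeset_registry()].
#' @return A `record_assessment`: `record_id`, `X` (missing mandatory
#'   items), `Y` (noncompliant coding items), `mandatory_flags`,
#'   `coding_flags`, `standard_bools`, `star`.
#' @export
assess_record <- function(record, config, registry) {
  stopifnot(inherits(config, "rule_config"))
  m <- assess_mandatory(record, config$mandatory_rules)
  c_ <- assess_coding(record, config$coding_rules, registry)
  record_assessment(record$record_id, m$flags, c_$flags, config$star_scheme)
}

# Build a record_assessment from flag vectors (shared with the generator,
# which knows its flags by construction).
record_assessment <- function(record_id, mandatory_flags, coding_flags,
                              scheme) {
  a <- list(record_id = record_id,
            X = sum(!mandatory_flags), Y = sum(!coding_flags),
            mandatory_flags = mandatory_flags, coding_flags = coding_flags)
  a$standard_bools <- evaluate_standards(a, scheme)
  a$star <- star_level(a$standard_bools, scheme)
  structure(a, class = "record_assessment")
}

#' @export
print.record_assessment <- function(x, ...) {
  cat("<record_assessment ", if (is.na(x$record_id)) "?" else x$record_id,
      ">: X = ", x$X, " missing, Y = ", x$Y, " noncompliant, ",
      x$star, " star\n", sep = "")
  invisible(x)
}

check_counts <- function(counts, k, what) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) {
    stop("cannot score an empty batch (n = 0)", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts > k) ||
      any(counts != trunc(counts))) {
    stop(what, " counts must be integers in [0, k = ", k, "]", call. = FALSE)
  }
  counts
}

#' Batch integrity score
#'
#' `Si = (1 - sum(X_i) / (n * k)) * 100`, where `X_i` is record i's count of
#' missing mandatory items and `k` the number of mandatory items. Always in
#' \[0, 100\]; an empty batch is an error (the formula divides by n), never a
#' silent 100.
#'
#' @param X Integer vector of per-record missing counts, each in `[0, k]`.
#' @param k Number of mandatory items (>= 1).
#' @return Numeric score in \[0, 100\], full precision.
#' @examples
#' integrity_score(c(1, 3), k = 4)  # 50
#' @export
integrity_score <- function(X, k) {
  stopifnot(length(k) == 1L, k >= 1L)
  X <- check_counts(X, k, "missing-item")
  (1 - sum(X) / (length(X) * k)) * 100
}

#' Batch coding score
#'
#' `Sc = (1 - sum(Y_i) / (n * k)) * 100`: identical contract to
#' [integrity_score()] with per-record noncompliant coding counts and the
#' number of coding items.
#'
#' @param Y Integer vector of per-record noncompliant counts, each in
#'   `[0, k]`.
#' @param k Number of coding items (>= 1).
#' @return Numeric score in \[0, 100\], full precision.
#' @export
coding_score <- function(Y, k) {
  stopifnot(length(k) == 1L, k >= 1L)
  Y <- check_counts(Y, k, "noncompliant-item")
  (1 - sum(Y) / (length(Y) * k)) * 100
}

#' Total score
#'
#' Weighted combination of the integrity and coding scores,
#' `St = w1 * Si + w2 * Sc`, default weights 0.5 / 0.5. Kept at full
#' precision; use [display_score()] for the reported whole-point value
#' (e.g. `total_score(75, 86)` is 80.5, displayed as 81).
#'
#' @param Si Integrity score in \[0, 100\].
#' @param Sc Coding score in \[0, 100\].
#' @param weights Length-2 non-negative weights summing to 1.
#' @return Numeric total score in \[0, 100\], full precision.
#' @export
total_score <- function(Si, Sc, weights = c(0.5, 0.5)) {
  stopifnot(length(Si) == 1L, length(Sc) == 1L,
            Si >= 0, Si <= 100, Sc >= 0, Sc <= 100)
  weights <- as.numeric(weights)
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be two non-negative numbers summing to 1",
         call. = FALSE)
  }
  weights[1L] * Si + weights[2L] * Sc
}

# Round half away from zero (base round() rounds half to even). Used only
# for displayed values.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Displayed whole-point score
#'
#' Scores are reported in whole points with half-up rounding: 80.5 is
#' displayed as 81.
#'
#' @param score Numeric score.
#' @return Integer displayed score.
#' @export
display_score <- function(score) as.integer(round_half_up(score))
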