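# Star rating: cumulative ordered standards, per-record star level, and the
# batch-level star aggregate.

#' One star-rating standard
#'
#' A standard is the conjunction of named rule flags: it holds iff every
#' referenced mandatory-item flag and every referenced coding flag is true.
#'
#' @param name Standard label.
#' @param mandatory Character vector of mandatory-rule item names.
#' @param coding Character vector of coding-rule item names.
#' @return A `star_standard` object.
#' @export
star_standard <- function(name, mandatory = character(0),
                          coding = character(0)) {
  if (length(mandatory) == 0L && length(coding) == 0L) {
    stop("standard ", sQuote(name), " references no rule flags",
         call. = FALSE)
  }
  structure(list(name = name, mandatory = as.character(mandatory),
                 coding = as.character(coding)),
            class = "star_standard")
}

#' Star-rating scheme
#'
#' An ordered list of standards plus cumulative thresholds: a record is rated
#' level L when the first `thresholds[L]` standards all hold. The default
#' scheme has 14 standards with thresholds 5/7/9/11/14 (1-5 stars);
#' a record failing the 1-star prefix is rated 0 stars.
#'
#' @param standards Ordered list of [star_standard()] objects.
#' @param thresholds Strictly increasing integer prefix lengths, one per star
#'   level (level = position); the last must equal `length(standards)`.
#' @return A `star_scheme` object.
#' @export
star_scheme <- function(standards, thresholds) {
  stopifnot(all(vapply(standards, inherits, logical(1L), "star_standard")))
  thresholds <- as.integer(thresholds)
  if (length(thresholds) < 1L || anyNA(thresholds) ||
      any(diff(thresholds) <= 0L) || thresholds[1L] < 1L) {
    stop("thresholds must be strictly increasing positive integers",
         call. = FALSE)
  }
  if (thresholds[length(thresholds)] != length(standards)) {
    stop("the top threshold (", thresholds[length(thresholds)],
         ") must equal the number of standards (", length(standards), ")",
         call. = FALSE)
  }
  nms <- vapply(standards, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop("standard names must be unique", call. = FALSE)
  }
  structure(list(standards = stats::setNames(standards, nms),
                 thresholds = thresholds),
            class = "star_scheme")
}

#' Default 14-standard star scheme
#'
#' Cumulative standards derived from the default mandatory and coding rules.
#' Standards 1-5 (1 star): name, ID number, age, gender code and location
#' present. 6-7 (2 stars): pathological nature present, at least one
#' four-diagnosis finding. 8-9 (3 stars): TCM symptom present, symptom code
#' present and within range. 10-11 (4 stars): TCM diagnosis present,
#' syndrome type and code present and within range. 12-14 (5 stars):
#' treatment present, treatment code present and within range,
#' dominant-disease code present and within range. The scheme is plain
#' configuration: replace it wholesale via [star_scheme()] or a rule
#' configuration file without code changes.
#'
#' @return A [star_scheme()] with thresholds 5, 7, 9, 11, 14.
#' @export
default_star_scheme <- function() {
  star_scheme(
    standards = list(
      star_standard("patient_name", mandatory = "name"),
      star_standard("id_number", mandatory = "id_number"),
      star_standard("age", mandatory = "age"),
      star_standard("gender_code", mandatory = "gender_code"),
      star_standard("location", mandatory = "location"),
      star_standard("pathological_nature", mandatory = "pathological_nature"),
      star_standard("four_diagnosis", mandatory = "four_diagnosis"),
      star_standard("tcm_symptom", mandatory = "tcm_symptom"),
      star_standard("tcm_symptom_code_valid",
                    mandatory = "tcm_symptom_code", coding = "disease_code"),
      star_standard("tcm_diagnosis", mandatory = "tcm_diagnosis"),
      star_standard("syndrome_type_and_code_valid",
                    mandatory = c("tcm_syndrome_type",
                                  "tcm_syndrome_type_code"),
                    coding = "syndrome_code"),
      star_standard("tcm_treatment", mandatory = "tcm_treatment"),
      star_standard("tcm_treatment_code_valid",
                    mandatory = "tcm_treatment_code",
                    coding = "therapeutic_method_code"),
      star_standard("dominant_disease_code_valid",
                    mandatory = "dominant_disease_code",
                    coding = c("dominant_disease_code", "disease_zheng_code"))
    ),
    thresholds = c(5L, 7L, 9L, 11L, 14L))
}

# Every rule name a scheme references must resolve in the configuration.
validate_scheme_references <- function(scheme, config) {
  stopifnot(inherits(scheme, "star_scheme"))
  mnames <- names(config$mandatory_rules)
  cnames <- names(config$coding_rules)
  for (st in scheme$standards) {
    bad_m <- setdiff(st$mandatory, mnames)
    bad_c <- setdiff(st$coding, cnames)
    if (length(bad_m) || length(bad_c)) {
      stop("star standard ", sQuote(st$name),
           " references unknown rule(s): ",
           paste(sQuote(c(bad_m, bad_c)), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Evaluate every scheme standard on one record's flags
#'
#' Pure function of the assessment flags: standard j is true iff all of its
#' referenced mandatory and coding flags are true.
#'
#' @param assessment A [assess_record()] result (or any list with named
#'   logical `mandatory_flags` and `coding_flags`).
#' @param scheme A [star_scheme()].
#' @return Named logical vector, one entry per standard, in scheme order.
#' @export
evaluate_standards <- function(assessment, scheme) {
  stopifnot(inherits(scheme, "star_scheme"))
  mf <- assessment$mandatory_flags
  cf <- assessment$coding_flags
  vapply(scheme$standards, function(st) {
    if (length(st$mandatory)) {
      v <- mf[st$mandatory]
      if (anyNA(v)) stop("standard ", sQuote(st$name),
                         " references an unknown mandatory rule",
                         call. = FALSE)
      if (!all(v)) return(FALSE)
    }
    if (length(st$coding)) {
      v <- cf[st$coding]
      if (anyNA(v)) stop("standard ", sQuote(st$name),
                         " references an unknown coding rule", call. = FALSE)
      if (!all(v)) return(FALSE)
    }
    TRUE
  }, logical(1L))
}

#' Star level of one record
#'
#' Returns the largest level L whose threshold-length prefix of standards is
#' fully satisfied, or 0 when even the level-1 prefix is broken. Standards
#' satisfied beyond a broken prefix never count: under the default scheme a
#' false standard 3 forces 0 stars even if standards 4-14 all hold.
#'
#' @param standard_bools Logical vector, one entry per scheme standard, in
#'   scheme order (e.g. from [evaluate_standards()]).
#' @param scheme A [star_scheme()].
#' @return Integer star level in `0:length(scheme$thresholds)`.
#' @export
star_level <- function(standard_bools, scheme) {
  stopifnot(inherits(scheme, "star_scheme"))
  b <- as.logical(standard_bools)
  if (length(b) != length(scheme$standards) || anyNA(b)) {
    stop("expected ", length(scheme$standards),
         " standard booleans, got ", length(standard_bools), call. = FALSE)
  }
  level <- 0L
  for (L in seq_along(scheme$thresholds)) {
    if (all(b[seq_len(scheme$thresholds[L])])) level <- L else break
  }
  level
}

#' Batch star level
#'
#' Aggregates a batch's per-record star levels into one overall star level:
#' the count-weighted mean level rounded half-up. This aggregate is a
#' reconstruction (the published description of the batch formula is
#' incomplete), so reports always carry the full star distribution alongside
#' it.
#'
#' @param star_counts Named non-negative counts for levels `"0"`..`"5"` (or
#'   `0:max_level` of the scheme in use); total must be >= 1.
#' @return Integer batch star level.
#' @export
batch_star <- function(star_counts) {
  counts <- as.numeric(star_counts)
  levels <- suppressWarnings(as.integer(names(star_counts)))
  if (anyNA(levels)) {
    stop("star_counts must be named by integer star level", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || sum(counts) < 1) {
    stop("star_counts must be non-negative with a positive total",
         call. = FALSE)
  }
  as.integer(round_half_up(sum(levels * counts) / sum(counts)))
}
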