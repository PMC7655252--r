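# Synthetic record batches with exact ground truth: records constructed to
# hit a target star level, with controlled missingness and code-validity
# corruption of the items the star target leaves free. All content is
# invented (fixture vocabularies and fixture code sets); no real patient
# data and no real standard codes.

#' Batch generation specification
#'
#' @param star_counts Named non-negative counts per target star level, e.g.
#'   `c("0" = 2, "5" = 3)`; an unnamed length-6 vector is taken as levels
#'   0-5. Total must be >= 1.
#' @param missingness Probability in \[0, 1\] that a mandatory item *not*
#'   pinned by the record's star target is blanked (default 0.15).
#' @param invalid_code_rate Probability in \[0, 1\] that a present, non-pinned
#'   coded item is given an out-of-range code (default 0.10).
#' @param seed Integer RNG seed; equal seeds give identical batches.
#' @return A `batch_spec` object.
#' @export
batch_spec <- function(star_counts, missingness = 0.15,
                       invalid_code_rate = 0.10, seed = 1L) {
  counts <- as.numeric(star_counts)
  if (is.null(names(star_counts))) {
    if (length(counts) != 6L) {
      stop("unnamed star_counts must have length 6 (levels 0-5)",
           call. = FALSE)
    }
    names(counts) <- as.character(0:5)
  } else {
    names(counts) <- names(star_counts)
  }
  lev <- suppressWarnings(as.integer(names(counts)))
  if (anyNA(lev) || any(lev < 0)) {
    stop("star_counts names must be non-negative integer levels",
         call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != trunc(counts)) ||
      sum(counts) < 1) {
    stop("star_counts must be non-negative integers with a positive total",
         call. = FALSE)
  }
  stopifnot(missingness >= 0, missingness <= 1,
            invalid_code_rate >= 0, invalid_code_rate <= 1)
  structure(list(star_counts = counts, missingness = missingness,
                 invalid_code_rate = invalid_code_rate,
                 seed = as.integer(seed)),
            class = "batch_spec")
}

# Invented vocabularies for free-text content.
.VOCAB <- list(
  location = c("East District Clinic", "Riverside Outpatient Dept",
               "North Gate Clinic", "Hillside TCM Center"),
  pathological_nature = c("deficiency", "excess", "mixed", "cold", "heat"),
  four_diagnosis = c("pale tongue with thin white coating", "wiry pulse",
                     "dull complexion", "low voice and shortness of breath",
                     "tenderness under palpation", "thready rapid pulse"),
  tcm_symptoms = c("fatigue", "night sweats", "dizziness", "poor appetite",
                   "insomnia", "palpitations", "cough", "epigastric pain"),
  tcm_diagnosis = c("deficiency pattern disorder", "stagnation disorder",
                    "damp-heat disorder", "wind-cold disorder"),
  syndrome_types = c("qi deficiency", "blood stasis", "damp-heat",
                     "yin deficiency", "liver qi stagnation"),
  treatments = c("tonify qi", "invigorate blood", "clear damp-heat",
                 "nourish yin", "soothe the liver"),
  names = c("Zhang San", "Li Si", "Wang Wu", "Zhao Liu", "Sun Qi",
            "Zhou Ba", "Wu Jiu", "Zheng Shi")
)

# Static generation context: per-field rule bindings, valid code pools
# (intersection over every code set bound to the field), and a guaranteed
# out-of-range code per field.
gen_context <- function(config, registry, scheme) {
  validate_config(config, registry)
  validate_scheme_references(scheme, config)
  fields <- list()
  touch <- function(f) {
    if (is.null(fields[[f]])) {
      fields[[f]] <<- list(mandatory = NA_character_,
                           coding = character(0), strict = logical(0))
    }
  }
  for (nm in names(config$mandatory_rules)) {
    f <- config$mandatory_rules[[nm]]$field_path
    touch(f)
    fields[[f]]$mandatory <- nm
  }
  for (nm in names(config$coding_rules)) {
    rule <- config$coding_rules[[nm]]
    f <- rule$field_path
    touch(f)
    fields[[f]]$coding <- c(fields[[f]]$coding, nm)
    fields[[f]]$strict <- c(fields[[f]]$strict, rule$strict)
  }
  for (f in names(fields)) {
    rules <- fields[[f]]$coding
    if (length(rules)) {
      sets <- lapply(rules, function(nm) {
        resolve_codeset(registry, config$coding_rules[[nm]]$codeset_id)$codes
      })
      pool <- Reduce(intersect, sets)
      if (length(pool) == 0L) {
        stop("generation target unreachable: no code satisfies every code ",
             "set bound to field ", sQuote(f), call. = FALSE)
      }
      fields[[f]]$pool <- pool
      union_codes <- unique(unlist(sets))
      bad <- "XX-OUT-OF-RANGE"
      while (bad %in% union_codes) bad <- paste0(bad, "X")
      fields[[f]]$invalid <- bad
    }
  }
  # fields each standard pins, in scheme order
  std_fields <- lapply(scheme$standards, function(st) {
    unique(c(
      vapply(st$mandatory, function(nm)
        config$mandatory_rules[[nm]]$field_path, character(1L)),
      vapply(st$coding, function(nm)
        config$coding_rules[[nm]]$field_path, character(1L))))
  })
  list(config = config, registry = registry, scheme = scheme,
       fields = fields, std_fields = std_fields)
}

# Draw 1-3 entries from a vocabulary.
draw_terms <- function(vocab) {
  sample(vocab, sample.int(3L, 1L))
}

# A fully conformant record plus its (all-TRUE) expected flags, held as a
# mutable working state.
perfect_state <- function(ctx, record_id) {
  cfg <- ctx$config
  values <- list(
    record_id = record_id,
    location = sample(.VOCAB$location, 1L),
    pathological_nature = sample(.VOCAB$pathological_nature, 1L),
    four_diagnosis = draw_terms(.VOCAB$four_diagnosis),
    tcm_symptoms = draw_terms(.VOCAB$tcm_symptoms),
    tcm_diagnosis = sample(.VOCAB$tcm_diagnosis, 1L),
    syndrome_types = draw_terms(.VOCAB$syndrome_types),
    treatments = draw_terms(.VOCAB$treatments),
    name = sample(.VOCAB$names, 1L),
    id_number = sprintf("SYN%012d", sample.int(.Machine$integer.max, 1L)),
    age = sample(0:95, 1L),
    dominant_disease_flag = sample(c("Y", "N"), 1L),
    admin_codes = list()
  )
  for (f in names(ctx$fields)) {
    pool <- ctx$fields[[f]]$pool
    if (is.null(pool)) next
    n_codes <- if (field_kind(f) == "list") sample.int(2L, 1L) else 1L
    codes <- sample(pool, n_codes, replace = TRUE)
    if (startsWith(f, "admin_codes.")) {
      values$admin_codes[[sub("^admin_codes\\.", "", f)]] <- codes
    } else if (field_kind(f) == "list") {
      values[[f]] <- unique(codes)
    } else {
      values[[f]] <- codes
    }
  }
  list(
    values = values,
    mflags = stats::setNames(rep(TRUE, length(cfg$mandatory_rules)),
                             names(cfg$mandatory_rules)),
    cflags = stats::setNames(rep(TRUE, length(cfg$coding_rules)),
                             names(cfg$coding_rules)))
}

# Blank a field: mandatory flag (if any) goes false; strict coding rules on
# the field go false; non-strict ones are compliant when absent.
blank_field <- function(state, ctx, field) {
  if (startsWith(field, "admin_codes.")) {
    state$values$admin_codes[[sub("^admin_codes\\.", "", field)]] <- NULL
  } else if (field_kind(field) == "list") {
    state$values[[field]] <- character(0)
  } else {
    state$values[[field]] <- NA
  }
  fi <- ctx$fields[[field]]
  if (!is.na(fi$mandatory)) state$mflags[[fi$mandatory]] <- FALSE
  if (length(fi$coding)) state$cflags[fi$coding] <- fi$strict == FALSE
  state
}

# Put an out-of-range code in a field: presence survives (mandatory flag
# untouched) but every coding rule on the field fails.
invalidate_field <- function(state, ctx, field) {
  fi <- ctx$fields[[field]]
  if (is.null(fi$invalid)) {
    stop("field ", sQuote(field), " carries no coding rule to violate",
         call. = FALSE)
  }
  if (startsWith(field, "admin_codes.")) {
    state$values$admin_codes[[sub("^admin_codes\\.", "", field)]] <-
      fi$invalid
  } else if (field_kind(field) == "list") {
    state$values[[field]] <- c(state$values[[field]][-1L], fi$invalid)
  } else {
    state$values[[field]] <- fi$invalid
  }
  state$cflags[fi$coding] <- FALSE
  state
}

#' Generate one record with a known star level
#'
#' Constructs a fully conformant record, then deliberately violates the
#' standard just past the target level's prefix (for targets below the top
#' level), and finally corrupts items outside the pinned prefix at the given
#' rates. The returned expected assessment is known by construction;
#' re-assessing the record with the same configuration reproduces it
#' exactly, including `star == target_star`.
#'
#' @param target_star Integer target level, `0:length(scheme$thresholds)`.
#' @param scheme A [star_scheme()].
#' @param config A [rule_config()].
#' @param registry A [codeset_registry()] (default: fixture sets).
#' @param record_id Identifier for the generated record.
#' @param missingness,invalid_code_rate Corruption rates for non-pinned
#'   items (defaults 0: only the deliberate violation).
#' @return List with `record` (an [outpatient_record()]) and `assessment`
#'   (the expected `record_assessment`).
#' @export
generate_record <- function(target_star, scheme = default_star_scheme(),
                            config = default_rule_config(),
                            registry = fixture_codeset_registry(),
                            record_id = "SYN-0001",
                            missingness = 0, invalid_code_rate = 0) {
  ctx <- gen_context(config, registry, scheme)
  generate_record_ctx(ctx, target_star, record_id, missingness,
                      invalid_code_rate)
}

generate_record_ctx <- function(ctx, target_star, record_id,
                                missingness, invalid_code_rate) {
  scheme <- ctx$scheme
  max_level <- length(scheme$thresholds)
  target_star <- as.integer(target_star)
  if (is.na(target_star) || target_star < 0L || target_star > max_level) {
    stop("target_star must be in 0..", max_level, call. = FALSE)
  }
  state <- perfect_state(ctx, record_id)

  prefix_len <- if (target_star == 0L) 0L else scheme$thresholds[target_star]
  violate_idx <- if (target_star < max_level) prefix_len + 1L else 0L
  protected <- unique(unlist(ctx$std_fields[seq_len(max(prefix_len,
                                                        violate_idx))]))
  if (violate_idx > 0L) {
    st <- scheme$standards[[violate_idx]]
    refs <- c(if (length(st$mandatory)) paste0("m:", st$mandatory),
              if (length(st$coding)) paste0("c:", st$coding))
    pick <- sample(refs, 1L)
    nm <- sub("^[mc]:", "", pick)
    if (startsWith(pick, "m:")) {
      state <- blank_field(state, ctx,
                           ctx$config$mandatory_rules[[nm]]$field_path)
    } else {
      state <- invalidate_field(state, ctx,
                                ctx$config$coding_rules[[nm]]$field_path)
    }
  }

  free <- setdiff(names(ctx$fields), protected)
  for (f in free) {
    fi <- ctx$fields[[f]]
    if (stats::runif(1L) < missingness) {
      state <- blank_field(state, ctx, f)
    } else if (length(fi$coding) &&
               stats::runif(1L) < invalid_code_rate) {
      state <- invalidate_field(state, ctx, f)
    }
  }

  assessment <- record_assessment(record_id, state$mflags, state$cflags,
                                  scheme)
  if (assessment$star != target_star) {
    stop("generation target unreachable: constructed record rates ",
         assessment$star, " star, not ", target_star,
         " (overlapping standards in a custom scheme?)", call. = FALSE)
  }
  rec <- do.call(outpatient_record, state$values)
  list(record = rec, assessment = assessment)
}

#' Generate a record batch with exact ground truth
#'
#' Builds `sum(spec$star_counts)` records whose star levels hit the
#' requested per-level targets exactly, shuffles them, and returns the
#' expected batch
#' assessment computed from the construction-time ground truth (per-record
#' X/Y counts feeding the integrity, coding and total score formulas).
#' Reproducible: equal seeds give identical batches.
#'
#' @param spec A [batch_spec()].
#' @param scheme A [star_scheme()].
#' @param config A [rule_config()].
#' @param registry A [codeset_registry()] (default: fixture sets).
#' @return List with `records`, `assessments` (expected per-record
#'   assessments, parallel to `records`) and `expected` (list: `n`, `Si`,
#'   `Sc`, `St`, `star_counts` over all scheme levels, `batch_star`).
#' @export
generate_batch <- function(spec, scheme = default_star_scheme(),
                           config = default_rule_config(),
                           registry = fixture_codeset_registry()) {
  stopifnot(inherits(spec, "batch_spec"))
  ctx <- gen_context(config, registry, scheme)
  max_level <- length(scheme$thresholds)
  lev <- as.integer(names(spec$star_counts))
  if (any(lev > max_level)) {
    stop("star_counts targets a level above the scheme's maximum (",
         max_level, ")", call. = FALSE)
  }
  set.seed(spec$seed)
  targets <- rep(lev, times = spec$star_counts)
  n <- length(targets)
  targets <- targets[sample.int(n)]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- generate_record_ctx(ctx, targets[i],
                                    record_id = sprintf("SYN-%06d", i),
                                    missingness = spec$missingness,
                                    invalid_code_rate =
                                      spec$invalid_code_rate)
  }
  records <- lapply(out, `[[`, "record")
  assessments <- lapply(out, `[[`, "assessment")
  X <- vapply(assessments, `[[`, numeric(1L), "X")
  Y <- vapply(assessments, `[[`, numeric(1L), "Y")
  stars <- vapply(assessments, `[[`, integer(1L), "star")
  counts <- stats::setNames(
    vapply(0:max_level, function(l) sum(stars == l), numeric(1L)),
    as.character(0:max_level))
  Si <- integrity_score(X, k_integrity(config))
  Sc <- coding_score(Y, k_coding(config))
  St <- total_score(Si, Sc, config$weights)
  list(records = records, assessments = assessments,
       expected = list(n = n, Si = Si, Sc = Sc, St = St,
                       star_counts = counts,
                       batch_star = batch_star(counts)))
}

#' Write records to a delimited or JSON-lines file
#'
#' Serializes a record list in a form [read_records()] parses back
#' losslessly.
#'
#' @param records List of [outpatient_record()] objects.
#' @param path Output file.
#' @param format `"csv"` or `"jsonl"`.
#' @param mapping A [default_field_mapping()].
#' @return Invisibly, `path`.
#' @export
write_records <- function(records, path, format = c("csv", "jsonl"),
                          mapping = default_field_mapping()) {
  format <- match.arg(format)
  rows <- lapply(records, serialize_record, mapping = mapping)
  if (format == "csv") {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- vapply(rows, function(r) {
      jsonlite::toJSON(as.list(r), auto_unbox = TRUE)
    }, character(1L))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
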