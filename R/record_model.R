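# Record data model: field registry, value normalization, parsing and
# serialization of structured outpatient encounters.

# Scalar free-text / code fields carried directly on the record.
.SCALAR_FIELDS <- c(
  "record_id", "location", "pathological_nature", "tcm_diagnosis",
  "name", "id_number", "gender_code", "dominant_disease_flag"
)

# Multi-valued fields; an empty vector means the item is missing.
.LIST_FIELDS <- c(
  "four_diagnosis", "tcm_symptoms", "tcm_symptom_codes",
  "syndrome_types", "syndrome_type_codes",
  "treatments", "treatment_codes", "dominant_disease_codes"
)

# Administrative code items (single code each) held in the admin_codes map.
.ADMIN_ITEMS <- c(
  "ethnicity", "medical_insurance_type", "disease_severity",
  "id_type", "diagnosis_type", "payment_method", "nationality"
)

#' Normalize a raw field value
#'
#' Strips surrounding whitespace and canonicalizes missing values: `NULL`,
#' `NA`, the empty string and whitespace-only strings all normalize to
#' `NA_character_`. The operation is idempotent. Codes are not case-folded:
#' code-system identifiers are case-defined.
#'
#' @param raw A raw value (character scalar, or `NULL`/`NA`).
#' @return A whitespace-stripped character scalar, or `NA_character_` when
#'   the value is missing.
#' @examples
#' normalize_value("  QiXu01 ")  # "QiXu01"
#' normalize_value("   ")        # NA
#' @export
normalize_value <- function(raw) {
  if (is.null(raw) || length(raw) == 0L) return(NA_character_)
  x <- as.character(raw[[1L]])
  if (is.na(x)) return(NA_character_)
  x <- trimws(x)
  if (!nzchar(x)) return(NA_character_)
  x
}

# Normalize a multi-valued field: blanks are dropped, so an all-blank input
# yields character(0) (item missing).
normalize_values <- function(raw) {
  if (is.null(raw) || length(raw) == 0L) return(character(0))
  vals <- vapply(as.character(raw), normalize_value, character(1L),
                 USE.NAMES = FALSE)
  vals[!is.na(vals)]
}

#' Construct an outpatient medical record
#'
#' Builds a normalized structured record for one patient encounter. All text
#' is whitespace-stripped; absent/empty/whitespace-only values become
#' missing; blank entries are dropped from multi-valued fields; `age`, when
#' present, must be a non-negative integer.
#'
#' @param record_id Opaque record identifier.
#' @param location,pathological_nature,tcm_diagnosis,name,id_number,gender_code,dominant_disease_flag
#'   Scalar text fields.
#' @param four_diagnosis,tcm_symptoms,tcm_symptom_codes,syndrome_types,syndrome_type_codes,treatments,treatment_codes,dominant_disease_codes
#'   Multi-valued fields (character vectors).
#' @param age Age in years (non-negative integer) or `NA`.
#' @param admin_codes Named list/vector of administrative codes; recognised
#'   names: `r paste(.ADMIN_ITEMS, collapse = ", ")`.
#' @return An object of class `outpatient_record`.
#' @export
outpatient_record <- function(record_id = NA, location = NA,
                              pathological_nature = NA,
                              four_diagnosis = character(0),
                              tcm_symptoms = character(0),
                              tcm_symptom_codes = character(0),
                              tcm_diagnosis = NA,
                              syndrome_types = character(0),
                              syndrome_type_codes = character(0),
                              treatments = character(0),
                              treatment_codes = character(0),
                              name = NA, id_number = NA, age = NA,
                              gender_code = NA,
                              dominant_disease_flag = NA,
                              dominant_disease_codes = character(0),
                              admin_codes = list()) {
  rec <- list()
  scal <- list(record_id = record_id, location = location,
               pathological_nature = pathological_nature,
               tcm_diagnosis = tcm_diagnosis, name = name,
               id_number = id_number, gender_code = gender_code,
               dominant_disease_flag = dominant_disease_flag)
  for (f in .SCALAR_FIELDS) rec[[f]] <- normalize_value(scal[[f]])
  lst <- list(four_diagnosis = four_diagnosis, tcm_symptoms = tcm_symptoms,
              tcm_symptom_codes = tcm_symptom_codes,
              syndrome_types = syndrome_types,
              syndrome_type_codes = syndrome_type_codes,
              treatments = treatments, treatment_codes = treatment_codes,
              dominant_disease_codes = dominant_disease_codes)
  for (f in .LIST_FIELDS) rec[[f]] <- normalize_values(lst[[f]])
  rec$age <- normalize_age(age)
  ac <- stats::setNames(rep(NA_character_, length(.ADMIN_ITEMS)), .ADMIN_ITEMS)
  for (nm in intersect(names(admin_codes), .ADMIN_ITEMS)) {
    ac[[nm]] <- normalize_value(admin_codes[[nm]])
  }
  rec$admin_codes <- as.list(ac)
  structure(rec, class = "outpatient_record")
}

normalize_age <- function(age) {
  x <- normalize_value(age)
  if (is.na(x)) return(NA_integer_)
  n <- suppressWarnings(as.numeric(x))
  if (is.na(n) || n < 0 || n != trunc(n)) {
    stop("age must be a non-negative integer, got ", sQuote(x), call. = FALSE)
  }
  as.integer(n)
}

#' @export
print.outpatient_record <- function(x, ...) {
  cat("<outpatient_record ", if (is.na(x$record_id)) "?" else x$record_id,
      ">\n", sep = "")
  for (f in .SCALAR_FIELDS) {
    cat("  ", format(f, width = 22), ": ",
        if (is.na(x[[f]])) "<missing>" else x[[f]], "\n", sep = "")
  }
  cat("  ", format("age", width = 22), ": ",
      if (is.na(x$age)) "<missing>" else x$age, "\n", sep = "")
  for (f in .LIST_FIELDS) {
    cat("  ", format(f, width = 22), ": ",
        if (length(x[[f]]) == 0L) "<missing>" else
          paste(x[[f]], collapse = " | "), "\n", sep = "")
  }
  n_admin <- sum(!vapply(x$admin_codes, is.na, logical(1L)))
  cat("  admin codes: ", n_admin, "/", length(.ADMIN_ITEMS), " present\n",
      sep = "")
  invisible(x)
}

# Resolve a field path ("name", "age", "tcm_symptoms", "admin_codes.ethnicity")
# against a record. Returns a character vector for list fields, a scalar
# (possibly NA) otherwise.
get_field <- function(record, path) {
  if (startsWith(path, "admin_codes.")) {
    item <- sub("^admin_codes\\.", "", path)
    if (!item %in% .ADMIN_ITEMS) {
      stop("unknown administrative code item ", sQuote(item), call. = FALSE)
    }
    return(record$admin_codes[[item]])
  }
  if (path == "age") return(record$age)
  if (!path %in% c(.SCALAR_FIELDS, .LIST_FIELDS)) {
    stop("field path ", sQuote(path),
         " does not resolve on an outpatient record", call. = FALSE)
  }
  record[[path]]
}

# Field kind: "scalar" or "list"; errors on unresolvable paths.
field_kind <- function(path) {
  if (path %in% .LIST_FIELDS) return("list")
  if (path %in% c(.SCALAR_FIELDS, "age")) return("scalar")
  if (startsWith(path, "admin_codes.") &&
      sub("^admin_codes\\.", "", path) %in% .ADMIN_ITEMS) {
    return("scalar")
  }
  stop("field path ", sQuote(path),
       " does not resolve on an outpatient record", call. = FALSE)
}

all_field_paths <- function() {
  c(.SCALAR_FIELDS, "age", .LIST_FIELDS,
    paste0("admin_codes.", .ADMIN_ITEMS))
}

#' Default field mapping for tabular input
#'
#' Binds source column names to record fields. The default maps every field
#' to a column of the same name (administrative codes as
#' `admin_codes.<item>`), with multi-valued cells joined by `"|"`.
#'
#' @param columns Named character vector overriding field -> column bindings;
#'   names are field paths, values are source column names.
#' @param delimiter Delimiter splitting multi-valued cells (default `"|"`).
#' @return A `field_mapping` object.
#' @export
default_field_mapping <- function(columns = character(0), delimiter = "|") {
  cols <- stats::setNames(all_field_paths(), all_field_paths())
  if (length(columns)) {
    bad <- setdiff(names(columns), all_field_paths())
    if (length(bad)) {
      stop("unknown record fields in mapping: ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
    }
    cols[names(columns)] <- columns
  }
  structure(list(columns = cols, delimiter = delimiter),
            class = "field_mapping")
}

#' Parse one raw row/object into a record
#'
#' Applies a field mapping to a named list of raw values (e.g. one CSV row or
#' one JSON-lines object), splitting multi-valued cells on the mapping's
#' delimiter and dropping blank entries. A malformed age (non-integer or
#' negative) is recorded as a parse warning and the field set missing rather
#' than failing the row.
#'
#' @param raw_fields Named list or character vector of raw values.
#' @param mapping A [default_field_mapping()] object.
#' @return A list with elements `record` (an [outpatient_record()]) and
#'   `warnings` (character vector, possibly empty).
#' @export
parse_record <- function(raw_fields, mapping = default_field_mapping()) {
  stopifnot(inherits(mapping, "field_mapping"))
  warnings <- character(0)
  args <- list()
  admin <- list()
  for (field in names(mapping$columns)) {
    col <- mapping$columns[[field]]
    if (!col %in% names(raw_fields)) next
    raw <- raw_fields[[col]]
    if (field == "age") {
      val <- normalize_value(raw)
      ok <- tryCatch({ normalize_age(val); TRUE }, error = function(e) FALSE)
      if (!ok) {
        warnings <- c(warnings, paste0(
          "malformed age ", sQuote(val), "; field set missing"))
        val <- NA_character_
      }
      args$age <- val
    } else if (startsWith(field, "admin_codes.")) {
      admin[[sub("^admin_codes\\.", "", field)]] <- raw
    } else if (field_kind(field) == "list") {
      args[[field]] <- split_multivalue(raw, mapping$delimiter)
    } else {
      args[[field]] <- raw
    }
  }
  args$admin_codes <- admin
  list(record = do.call(outpatient_record, args), warnings = warnings)
}

split_multivalue <- function(raw, delimiter) {
  if (length(raw) > 1L) return(normalize_values(raw))
  x <- normalize_value(raw)
  if (is.na(x)) return(character(0))
  strsplit(x, delimiter, fixed = TRUE)[[1L]]
}

#' Serialize a record to one flat row
#'
#' Inverse of [parse_record()]: emits a named character vector (one cell per
#' mapped column), joining multi-valued fields with the mapping delimiter.
#' `parse_record(serialize_record(r))` is the identity on any record already
#' satisfying the model invariants.
#'
#' @param record An [outpatient_record()].
#' @param mapping A [default_field_mapping()] object.
#' @return Named character vector; missing cells are empty strings.
#' @export
serialize_record <- function(record, mapping = default_field_mapping()) {
  stopifnot(inherits(record, "outpatient_record"))
  out <- character(0)
  for (field in names(mapping$columns)) {
    col <- mapping$columns[[field]]
    val <- get_field(record, field)
    cell <- if (field_kind(field) == "list") {
      paste(val, collapse = mapping$delimiter)
    } else if (is.na(val)) "" else as.character(val)
    out[[col]] <- cell
  }
  out
}
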