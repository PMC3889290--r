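# Cohort container, delimited-table I/O, scoring and exclusion rules.
#
# A cohort is a plain data.frame (class c("cohort", "data.frame")) with one
# row per patient.  Clinical categoricals are stored as character using the
# canonical spellings below; IHC scores are integer 0..3 or NA, one column
# per receptor/compartment (her2 is membrane-only; her3 membrane exists but
# is near-absent in gastric tumours).

.cohort_levels <- list(
  sex             = c("male", "female"),
  lauren          = c("intestinal", "diffuse", "mixed"),
  location        = c("stomach", "egj"),
  radicality      = c("R0", "R1", "R2"),
  lymphadenectomy = c("D0", "D1", "D2", "NR"),
  pt              = c("Tis", "T1", "T2", "T3", "T4"),
  pn              = c("N0", "N1", "N2", "N3"),
  stage           = c("0", "IA", "IB", "II", "IIIA", "IIIB", "IVM0", "IVM1"),
  adjuvant        = c("surgery_alone", "chemoradiotherapy")
)

#' IHC marker columns of a cohort table
#'
#' Column names for the receptor/compartment immunohistochemistry scores
#' carried by a cohort: HER1/HER3/HER4 are scored in membrane and cytoplasm,
#' HER2 in membrane only.
#'
#' @return character vector of column names.
#' @export
marker_columns <- function() {
  c("her1_membrane", "her1_cytoplasm", "her2_membrane", "her3_membrane",
    "her3_cytoplasm", "her4_membrane", "her4_cytoplasm")
}

.mandatory_cols <- c("id", "time_months", "event")

#' Construct a cohort from a data.frame
#'
#' Validates the invariants of the container: unique ids, non-negative
#' follow-up times, 0/1 event indicators, postoperative deaths flagged only
#' among deaths, and IHC scores in 0..3 or missing.
#'
#' @param df data.frame with at least columns `id`, `time_months`, `event`.
#' @param provenance free-text source tag stored as an attribute.
#' @return object of class `cohort`.
#' @export
as_cohort <- function(df, provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.mandatory_cols, names(df))
  if (length(missing_cols))
    stop("mandatory column(s) missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("patient ids are not unique: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  df$time_months <- as.numeric(df$time_months)
  bad_t <- which(!is.na(df$time_months) & df$time_months < 0)
  if (length(bad_t))
    stop("negative time_months at row id(s): ",
         paste(df$id[bad_t], collapse = ", "), call. = FALSE)
  df$event <- as.integer(df$event)
  if (any(!df$event %in% c(0L, 1L, NA)))
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  if (!is.null(df$postop_death)) {
    df$postop_death <- as.integer(df$postop_death)
    bad <- which(df$postop_death == 1L & df$event != 1L)
    if (length(bad))
      stop("postop_death = 1 requires event = 1 (row id(s): ",
           paste(df$id[bad], collapse = ", "), ")", call. = FALSE)
  }
  for (m in intersect(marker_columns(), names(df))) {
    df[[m]] <- suppressWarnings(as.integer(df[[m]]))
    if (any(!is.na(df[[m]]) & !df[[m]] %in% 0:3))
      stop("IHC score outside 0..3 in column ", m, call. = FALSE)
  }
  structure(df, class = c("cohort", "data.frame"), provenance = provenance)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients (source: %s)\n", nrow(x),
              attr(x, "provenance") %||% "unspecified"))
  if (!is.null(x$event))
    cat(sprintf("  events: %d, censored: %d\n",
                sum(x$event == 1, na.rm = TRUE), sum(x$event == 0, na.rm = TRUE)))
  mk <- intersect(marker_columns(), names(x))
  if (length(mk))
    cat("  IHC scores present for: ", paste(mk, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# normalize one categorical column against its canonical levels,
# case-insensitively; unmatched non-empty values become NA with a warning.
.normalize_level <- function(x, levels, column) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  idx <- match(tolower(x), tolower(levels))
  out <- levels[idx]
  bad <- !is.na(x) & is.na(idx)
  if (any(bad)) {
    warning(sprintf("column '%s': %d unparseable value(s) (%s) recorded as missing",
                    column, sum(bad),
                    paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read a patient cohort from a delimited file
#'
#' Reads a flat table (comma default, tab accepted) with one row per patient,
#' maps columns through an optional schema, normalizes categorical spellings
#' case-insensitively, and validates the container invariants.  Unparseable
#' categorical levels are recorded as missing with a warning; a missing
#' mandatory column or a negative survival time is a hard error.
#'
#' @param path path to a CSV/TSV file.
#' @param schema_config optional named character vector mapping canonical
#'   column names (names) to file column names (values), e.g.
#'   `c(time_months = "os_months")`.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return a `cohort`; the validation summary (row count, per-column warning
#'   counts) is attached as attribute `"validation"`.
#' @export
read_cohort <- function(path, schema_config = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           check.names = FALSE)
  if (!is.null(schema_config)) {
    schema_config <- unlist(schema_config)
    for (canonical in names(schema_config)) {
      file_col <- schema_config[[canonical]]
      if (!file_col %in% names(raw))
        stop("schema_config maps '", canonical, "' to absent column '",
             file_col, "'", call. = FALSE)
      names(raw)[names(raw) == file_col] <- canonical
    }
  }
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols))
    stop("mandatory column(s) missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n_warn <- integer(0)
  for (col in intersect(names(.cohort_levels), names(raw))) {
    wcount <- 0L
    withCallingHandlers(
      raw[[col]] <- .normalize_level(raw[[col]], .cohort_levels[[col]], col),
      warning = function(w) {
        wcount <<- wcount + 1L
        warning(w)
        invokeRestart("muffleWarning")
      })
    if (wcount) n_warn[col] <- wcount
  }
  for (m in intersect(marker_columns(), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[m]]))
    bad <- !is.na(v) & !v %in% 0:3
    if (any(bad)) {
      warning(sprintf("column '%s': %d score(s) outside 0..3 recorded as missing",
                      m, sum(bad)), call. = FALSE)
      v[bad] <- NA_real_
    }
    raw[[m]] <- as.integer(v)
  }
  cohort <- as_cohort(raw, provenance = path)
  attr(cohort, "validation") <- list(
    path = path, n_rows = nrow(raw), separator = sep,
    columns = names(raw), normalization_warnings = as.list(n_warn))
  cohort
}

#' Write a cohort to a delimited file
#'
#' Inverse of [read_cohort()]: all non-missing fields round-trip exactly
#' (times are written with full precision; missing values as empty cells).
#'
#' @param cohort a `cohort`.
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), NA, format(x, digits = 15, scientific = FALSE, trim = TRUE)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Dichotomize an ordinal IHC score into a binary marker call
#'
#' Staining scores 0 and 1+ are negative, 2+ and 3+ positive; missing stays
#' missing.  This is the standard positivity rule for HER-family
#' immunohistochemistry.
#'
#' @param score integer vector of scores in 0..3, NA allowed.
#' @return logical vector: `TRUE` positive, `FALSE` negative, `NA` missing.
#' @export
#' @examples
#' dichotomize_ihc(c(0, 1, 2, 3, NA))
dichotomize_ihc <- function(score) {
  score <- as.numeric(score)
  if (any(!is.na(score) & !score %in% 0:3))
    stop("IHC score outside 0..3: ",
         paste(unique(score[!is.na(score) & !score %in% 0:3]), collapse = ", "),
         call. = FALSE)
  score >= 2
}

#' Binary marker calls for one receptor/compartment
#'
#' @param cohort a `cohort`.
#' @param marker one of [marker_columns()].
#' @return logical vector aligned with the cohort rows.
#' @export
marker_call <- function(cohort, marker) {
  marker <- match.arg(marker, marker_columns())
  if (!marker %in% names(cohort))
    stop("cohort has no column '", marker, "'", call. = FALSE)
  dichotomize_ihc(cohort[[marker]])
}

#' Exclude postoperative deaths from survival analysis
#'
#' Deaths during the postoperative period reflect surgical mortality, not
#' disease course, and are removed before any survival modelling.  The
#' operation is idempotent and leaves the input unmodified.
#'
#' @param cohort a `cohort` with a populated `postop_death` flag.
#' @return the sub-cohort with `postop_death == 0`.
#' @export
exclude_postoperative_deaths <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$postop_death))
    stop("cohort has no 'postop_death' column", call. = FALSE)
  keep <- cohort$postop_death %in% 0L  # NA treated as not flagged
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("all records flagged as postoperative deaths: empty cohort returned",
            call. = FALSE)
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- class(cohort)
  out
}

#' Collapse TNM stage into the three analysis groups
#'
#' Stages 0/IA/IB/II form the early group, IIIA/IIIB/IV M0 the locally
#' advanced group, and IV M1 (metastatic disease) its own group.
#'
#' @param stage character vector of stages
#'   (`"0","IA","IB","II","IIIA","IIIB","IVM0","IVM1"`); NA allowed.
#' @return factor with levels `g0_I_II`, `gIII_IVM0`, `gIVM1`.
#' @export
assign_stage_group <- function(stage) {
  stage <- as.character(stage)
  map <- c("0" = "g0_I_II", IA = "g0_I_II", IB = "g0_I_II", II = "g0_I_II",
           IIIA = "gIII_IVM0", IIIB = "gIII_IVM0", IVM0 = "gIII_IVM0",
           IVM1 = "gIVM1")
  bad <- !is.na(stage) & !stage %in% names(map)
  if (any(bad))
    stop("unknown stage value(s): ", paste(unique(stage[bad]), collapse = ", "),
         call. = FALSE)
  factor(unname(map[stage]), levels = c("g0_I_II", "gIII_IVM0", "gIVM1"))
}

#' Cohort column dictionary
#'
#' @return data.frame documenting every cohort column, its type and coding.
#' @export
cohort_dictionary <- function() {
  path <- system.file("extdata", "data_dictionary.tsv", package = "curemix",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
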