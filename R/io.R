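#' Read a cohort of nodule observations
#'
#' Reads a delimited-text cohort file (comma or tab, auto-detected from
#' the header line) with the columns `screenee_id`, `nodule_id`,
#' `timepoint`, `days_from_baseline`, `max_diameter_mm`,
#' `measured_volume_mm3` in any order. An empty volume field marks a
#' nodule not re-measured at follow-up. The reader validates the
#' schema and raises structured errors naming the offending file lines
#' for non-numeric fields, duplicate `(screenee, nodule, timepoint)`
#' keys, non-positive measurements, and baseline rows with nonzero
#' `days_from_baseline`.
#'
#' @param path Path to the cohort file.
#' @return A tibble in canonical column order.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(
    path, delim = delim, na = c("", "NA"), show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("screenee_id", "nodule_id", "timepoint",
                "days_from_baseline", "max_diameter_mm",
                "measured_volume_mm3")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[required]

  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at file line(s) %s",
                   col, paste(bad + 1L, collapse = ", ")), call. = FALSE)
    out
  }
  out <- tibble::tibble(
    screenee_id = df$screenee_id,
    nodule_id = df$nodule_id,
    timepoint = as.integer(parse_num(df$timepoint, "timepoint")),
    days_from_baseline = as.integer(
      parse_num(df$days_from_baseline, "days_from_baseline")),
    max_diameter_mm = parse_num(df$max_diameter_mm, "max_diameter_mm"),
    measured_volume_mm3 = parse_num(df$measured_volume_mm3,
                                    "measured_volume_mm3")
  )
  validate_cohort(out)
  out
}

# schema invariants shared by the reader and the writer; line numbers
# reported are 1-based file lines (header = line 1)
validate_cohort <- function(x) {
  line <- seq_len(nrow(x)) + 1L
  if (anyNA(x$screenee_id) || anyNA(x$nodule_id) || anyNA(x$timepoint) ||
      anyNA(x$days_from_baseline))
    stop("identifier, timepoint and days columns must not be missing",
         call. = FALSE)
  key <- paste(x$screenee_id, x$nodule_id, x$timepoint, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (screenee_id, nodule_id, timepoint) at file line(s) ",
         paste(line[dup], collapse = ", "), call. = FALSE)
  bad <- which(x$timepoint == 0 & x$days_from_baseline != 0)
  if (length(bad))
    stop("baseline rows must have days_from_baseline = 0: line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  bad <- which(x$max_diameter_mm <= 0 | is.na(x$max_diameter_mm))
  if (length(bad))
    stop("max_diameter_mm must be positive: line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  bad <- which(!is.na(x$measured_volume_mm3) & x$measured_volume_mm3 <= 0)
  if (length(bad))
    stop("measured_volume_mm3 must be positive when present: line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  bad <- which(x$days_from_baseline < 0)
  if (length(bad))
    stop("days_from_baseline must be non-negative: line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Write a cohort of nodule observations
#'
#' Writes the canonical cohort columns as delimited text (missing
#' follow-up volumes become empty fields). Generator-internal columns
#' (names starting with a dot) are dropped.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  stopifnot(is.data.frame(cohort), delim %in% c(",", "\t"))
  cols <- c("screenee_id", "nodule_id", "timepoint", "days_from_baseline",
            "max_diameter_mm", "measured_volume_mm3")
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("cohort lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  readr::write_delim(cohort[cols], path, delim = delim, na = "")
  invisible(path)
}

#' Published-style cross-classification fixture tables
#'
#' The four 3x3 count tables of measured-volume (rows) versus
#' estimated-volume (columns) categories that the package reproduces:
#' LDCT outcome and VDT category, each at nodule (PN) and screenee
#' level. Grand totals are 2715, 2311, 1583 and 1347 respectively.
#'
#' @return A named list of [contingency_table()] objects: `pn_ldct`,
#'   `pn_vdt`, `screenee_ldct`, `screenee_vdt`.
#' @examples
#' fixture_tables()$pn_ldct
#' @export
fixture_tables <- function() {
  dir <- system.file("extdata", package = "nodulevol", mustWork = TRUE)
  lab <- list(ldct = outcome_levels(), vdt = vdt_levels())
  out <- list(
    pn_ldct = read_count_matrix(file.path(dir, "pn_ldct.csv"), lab$ldct),
    pn_vdt = read_count_matrix(file.path(dir, "pn_vdt.csv"), lab$vdt),
    screenee_ldct = read_count_matrix(file.path(dir, "screenee_ldct.csv"),
                                      lab$ldct),
    screenee_vdt = read_count_matrix(file.path(dir, "screenee_vdt.csv"),
                                     lab$vdt)
  )
  out
}

#' Read / write a labelled count matrix
#'
#' Count matrices are stored as CSV with a leading label column (row
#' categories) and one column per column category, matching the fixture
#' layout.
#'
#' @param path File path.
#' @param labels Optional expected category labels; an error is raised
#'   if the file's labels differ (in content or order).
#' @return `read_count_matrix()` returns a [contingency_table()];
#'   `write_count_matrix()` returns `path` invisibly.
#' @export
read_count_matrix <- function(path, labels = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  if (!is.null(labels) &&
      (!identical(rownames(m), labels) || !identical(colnames(m), labels)))
    stop("count matrix labels do not match the expected categories",
         call. = FALSE)
  contingency_table(m)
}

#' @rdname read_count_matrix
#' @param table A `contingency_table` to write.
#' @export
write_count_matrix <- function(table, path) {
  if (!inherits(table, "contingency_table"))
    table <- contingency_table(table)
  df <- tibble::as_tibble(as.data.frame(unclass(table)))
  df <- tibble::add_column(df, category = rownames(table), .before = 1)
  readr::write_csv(df, path)
  invisible(path)
}
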