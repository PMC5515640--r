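#' Read QST z-profiles from a CSV file
#'
#' Reads a comma-separated, UTF-8 file with a header row and one row per
#' subject. Parameter columns are matched case-insensitively against the 13
#' QST codes (see [qst_parameters()]); non-standard column names can be mapped
#' with `column_map`. Empty cells are missing values. PHS must be in
#' `{0, 2}` and DMA in `{0, 2, 3}` (or missing); violations raise an error
#' naming the row and column. A parse report with the number of missing cells
#' per parameter is attached as attribute `"parse_report"`.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional named character vector mapping file column names
#'   to parameter codes (or to `"subject_id"` / `"etiology"`), e.g.
#'   `c(cold_det = "CDT")`.
#' @return A tibble of QST profiles: `subject_id` (character), `etiology`
#'   (character or `NA`), and the 13 numeric parameter columns in standard
#'   order. Rows preserve the file order.
#' @seealso [write_profiles()], [validate_profiles()]
#' @export
read_profiles <- function(path, column_map = NULL) {
  # parse everything as text, then convert via base strtod (correctly-rounded
  # doubles, so write_profiles() -> read_profiles() round-trips bit-exactly)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  nm <- names(raw)
  if (!is.null(column_map)) {
    hit <- nm %in% names(column_map)
    nm[hit] <- unname(column_map[nm[hit]])
  }
  canon <- toupper(nm)
  params <- qst_param_codes()
  names(raw) <- ifelse(canon %in% params, canon,
                       ifelse(tolower(nm) %in% c("subject_id", "id", "subject"),
                              "subject_id",
                              ifelse(tolower(nm) == "etiology", "etiology", nm)))
  unknown <- setdiff(names(raw), c("subject_id", "etiology", params,
                                   "true_phenotype", "is_patient"))
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "Unrecognized column(s): ", paste(unknown, collapse = ", "),
      ". Map them to parameter codes with `column_map` or drop them."
    ))
  }
  if (!"subject_id" %in% names(raw)) {
    rlang::abort("Profiles file must contain a subject id column (subject_id/id/subject).")
  }
  raw$subject_id <- as.character(raw$subject_id)
  if (!"etiology" %in% names(raw)) raw$etiology <- NA_character_
  for (p in setdiff(params, names(raw))) raw[[p]] <- NA_real_
  out <- dplyr::select(raw, "subject_id", "etiology", dplyr::all_of(params))
  for (p in params) {
    v <- out[[p]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & nzchar(trimws(v)) & is.na(num))
      if (length(bad) > 0) {
        rlang::abort(sprintf("Non-numeric %s value '%s' in row %d.",
                             p, v[bad[1]], bad[1]))
      }
      out[[p]] <- num
    }
  }
  out <- validate_profiles(out)
  report <- tibble::tibble(
    parameter = params,
    n_missing = vapply(params, function(p) sum(is.na(out[[p]])), integer(1))
  )
  attr(out, "parse_report") <- report
  out
}

#' Validate a tibble of QST profiles
#'
#' Checks the profile invariants: PHS in `{0, 2}`, DMA in `{0, 2, 3}`,
#' continuous z-values finite, and at least one non-missing parameter per
#' subject. Errors name the offending row and column.
#'
#' @param profiles A data frame with `subject_id` and the 13 parameter
#'   columns (missing parameter columns are added as all-missing).
#' @return The validated profiles as a tibble with columns in standard order.
#' @export
validate_profiles <- function(profiles) {
  params <- qst_param_codes()
  profiles <- tibble::as_tibble(profiles)
  if (!"subject_id" %in% names(profiles)) {
    rlang::abort("`profiles` must have a `subject_id` column.")
  }
  if (!"etiology" %in% names(profiles)) profiles$etiology <- NA_character_
  for (p in setdiff(params, names(profiles))) profiles[[p]] <- NA_real_
  check_codes <- function(col, allowed) {
    v <- profiles[[col]]
    bad <- which(!is.na(v) & !v %in% allowed)
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "Invalid %s code %s in row %d (subject %s); allowed: {%s} or missing.",
        col, format(v[bad[1]]), bad[1], profiles$subject_id[bad[1]],
        paste(allowed, collapse = ", ")
      ))
    }
  }
  check_codes("PHS", c(0, 2))
  check_codes("DMA", c(0, 2, 3))
  for (p in setdiff(params, c("PHS", "DMA"))) {
    v <- profiles[[p]]
    bad <- which(!is.na(v) & !is.finite(v))
    if (length(bad) > 0) {
      rlang::abort(sprintf("Non-finite %s value in row %d (subject %s).",
                           p, bad[1], profiles$subject_id[bad[1]]))
    }
  }
  zmat <- as.matrix(profiles[, params])
  empty <- which(rowSums(!is.na(zmat)) == 0)
  if (length(empty) > 0) {
    rlang::abort(sprintf(
      "Subject %s (row %d) has no non-missing QST value.",
      profiles$subject_id[empty[1]], empty[1]
    ))
  }
  front <- intersect(c("subject_id", "etiology", "true_phenotype"), names(profiles))
  dplyr::select(profiles, dplyr::all_of(front), dplyr::all_of(params))
}

#' Write QST profiles to a CSV file
#'
#' Inverse of [read_profiles()]: non-missing values round-trip bit-exactly
#' (full precision), missing cells are written empty.
#'
#' @param profiles A profiles tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  out <- tibble::as_tibble(profiles)
  # %.17g guarantees exact binary round-trip of doubles through text
  for (p in intersect(qst_param_codes(), names(out))) {
    v <- out[[p]]
    out[[p]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}
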