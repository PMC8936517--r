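#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical long-format plate table: one row per well.
plate_table_cols <- c(
  "plate_id", "well", "sample_id",
  "drug1", "conc1_nM", "drug2", "conc2_nM", "drug3", "conc3_nM",
  "role", "signal"
)

well_roles <- c("negative_control", "positive_control", "treated")

#' Format a well label
#'
#' @param row row letter "A".."P" (character).
#' @param col column number 1..24.
#' @return zero-padded label such as `"A01"`.
#' @export
well_label <- function(row, col) sprintf("%s%02d", row, as.integer(col))

#' Parse well labels into row letter and column number
#'
#' Accepts both `"A1"` and `"A01"` dialects; rows A-P, columns 1-24
#' (384-well plate).
#'
#' @param well character vector of well labels.
#' @return tibble with columns `row`, `col`.
#' @export
parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-P])([0-9]{1,2})$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  row <- ifelse(bad, NA_character_, vapply(m, function(x) x[2], "", USE.NAMES = FALSE))
  col <- ifelse(bad, NA_integer_, as.integer(vapply(m, function(x) x[3], "", USE.NAMES = FALSE)))
  bad <- bad | is.na(col) | col < 1L | col > 24L
  if (any(bad)) {
    stop("malformed well label(s): ", paste(unique(well[bad]), collapse = ", "),
         call. = FALSE)
  }
  tibble(row = row, col = col)
}

#' Canonical label for a well's treatment
#'
#' Drug names joined with their concentrations, e.g.
#' `"bortezomib@4+dexamethasone@10"`; control wells get their role name.
#' Drugs are kept in column order (drug1 is the design's first drug).
#'
#' @param wells a plate table (tibble).
#' @return character vector of labels.
#' @export
treatment_label <- function(wells) {
  lab <- character(nrow(wells))
  for (i in seq_len(nrow(wells))) {
    if (wells$role[i] != "treated") {
      lab[i] <- wells$role[i]
    } else {
      parts <- character(0)
      for (k in 1:3) {
        d <- wells[[paste0("drug", k)]][i]
        cc <- wells[[paste0("conc", k, "_nM")]][i]
        if (!is.na(d) && nzchar(d)) {
          parts <- c(parts, paste0(d, "@", format(cc, trim = TRUE, scientific = FALSE)))
        }
      }
      lab[i] <- paste(parts, collapse = "+")
    }
  }
  lab
}

#' Combination label ignoring concentrations
#'
#' Drug names only, joined with `+`; used to group titration series.
#' @param wells a plate table.
#' @return character vector.
#' @export
drug_set_label <- function(wells) {
  lab <- character(nrow(wells))
  for (i in seq_len(nrow(wells))) {
    if (wells$role[i] != "treated") {
      lab[i] <- wells$role[i]
    } else {
      ds <- c(wells$drug1[i], wells$drug2[i], wells$drug3[i])
      ds <- ds[!is.na(ds) & nzchar(ds)]
      lab[i] <- paste(ds, collapse = "+")
    }
  }
  lab
}

validate_plate_table <- function(wells) {
  stopifnot(is.data.frame(wells))
  missing_cols <- setdiff(plate_table_cols, names(wells))
  if (length(missing_cols) > 0) {
    stop("plate table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  where <- function(i) paste0("plate ", wells$plate_id[i], ", well ", wells$well[i])

  dup <- duplicated(wells[, c("plate_id", "well")])
  if (any(dup)) {
    stop("duplicate well(s): ", paste(unique(sapply(which(dup), where)), collapse = "; "),
         call. = FALSE)
  }
  bad_role <- !(wells$role %in% well_roles)
  if (any(bad_role)) {
    i <- which(bad_role)[1]
    stop("invalid role '", wells$role[i], "' at ", where(i), call. = FALSE)
  }
  bad_sig <- !is.finite(wells$signal) | wells$signal < 0
  if (any(bad_sig)) {
    i <- which(bad_sig)[1]
    stop("negative or non-finite signal at ", where(i), call. = FALSE)
  }
  for (i in seq_len(nrow(wells))) {
    drugs <- c(wells$drug1[i], wells$drug2[i], wells$drug3[i])
    concs <- c(wells$conc1_nM[i], wells$conc2_nM[i], wells$conc3_nM[i])
    present <- !is.na(drugs) & nzchar(drugs)
    if (wells$role[i] == "treated" && !any(present)) {
      stop("treated well without drugs at ", where(i), call. = FALSE)
    }
    if (wells$role[i] != "treated" && any(present)) {
      stop("control well with drugs at ", where(i), call. = FALSE)
    }
    if (any(present)) {
      if (anyDuplicated(drugs[present])) {
        stop("duplicate drug names within one well at ", where(i), call. = FALSE)
      }
      cc <- concs[present]
      if (any(!is.finite(cc) | cc <= 0)) {
        stop("missing or non-positive concentration for a listed drug at ",
             where(i), call. = FALSE)
      }
    }
    if (any(!is.na(concs[!present]))) {
      stop("concentration given for an absent drug at ", where(i), call. = FALSE)
    }
  }
  invisible(wells)
}

#' Read the canonical long-format plate table
#'
#' Comma-separated, UTF-8, header mandatory, columns `plate_id, well,
#' sample_id, drug1, conc1_nM, drug2, conc2_nM, drug3, conc3_nM, role,
#' signal`. Empty drug fields denote absent drugs; concentrations are in nM.
#' Well labels accept `"A1"` or `"A01"` and are re-emitted zero-padded.
#'
#' @param path file path.
#' @return tibble of wells with parsed `row`/`col` columns and logical QC flag
#'   columns `qc_outlier`, `qc_excluded` (initialized `FALSE`), ordered by
#'   plate then position. One plate = one distinct `plate_id`; use
#'   [split_plates()] for a per-plate list.
#' @export
read_plate_table <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      well = readr::col_character(),
      sample_id = readr::col_character(),
      drug1 = readr::col_character(),
      conc1_nM = readr::col_double(),
      drug2 = readr::col_character(),
      conc2_nM = readr::col_double(),
      drug3 = readr::col_character(),
      conc3_nM = readr::col_double(),
      role = readr::col_character(),
      signal = readr::col_double()
    ),
    progress = FALSE, locale = readr::locale(decimal_mark = ".")
  )
  pos <- parse_well(raw$well)
  wells <- dplyr::bind_cols(raw, pos)
  wells$well <- well_label(wells$row, wells$col)
  for (k in paste0("drug", 1:3)) {
    wells[[k]][!is.na(wells[[k]]) & !nzchar(wells[[k]])] <- NA_character_
  }
  validate_plate_table(wells)
  wells$qc_outlier <- FALSE
  wells$qc_excluded <- FALSE
  dplyr::arrange(wells, .data$plate_id, .data$row, .data$col)
}

#' Write the canonical plate table
#'
#' Inverse of [read_plate_table()]: only the canonical columns are written,
#' well labels zero-padded, concentrations in nM, empty fields for absent
#' drugs.
#'
#' @param wells plate table (tibble with at least the canonical columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(wells, path) {
  validate_plate_table(wells)
  out <- wells[, plate_table_cols]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a result table
#'
#' Generic delimited-text writer for downstream result tables (QC reports,
#' curve tables, DSS and synergy summaries, cluster labels): comma-separated
#' with a stable column order and full floating-point precision, so that
#' write-then-read round-trips.
#'
#' @param records data frame of results (may have zero rows: a header-only
#'   file is written).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  readr::write_csv(as_tibble(records), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path file path.
#' @return tibble with column types guessed from the full file.
#' @export
read_results <- function(path) {
  readr::read_csv(path, col_types = readr::cols(), guess_max = Inf,
                  progress = FALSE)
}

#' Split a well table into a list of plates
#'
#' @param wells plate table.
#' @return named list of tibbles, one per `plate_id`.
#' @export
split_plates <- function(wells) {
  split(wells, wells$plate_id)
}

#' Check a plate's control complement
#'
#' A plate needs at least 2 negative-control and 2 positive-control wells to
#' be normalizable.
#'
#' @param plate well table for one plate.
#' @return logical scalar.
#' @export
has_controls <- function(plate) {
  sum(plate$role == "negative_control") >= 2 &&
    sum(plate$role == "positive_control") >= 2
}
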