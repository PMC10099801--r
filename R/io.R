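#' Read long-format capture records
#'
#' Reads a CSV of one row per capture (individual, year, observed SVL, sex)
#' and assembles a [capture_data()] object. Years are mapped to occasions
#' 1..T by the sorted order of the distinct years present. Duplicate
#' within-year records for an individual are collapsed to a single annual
#' detection keeping the first SVL measurement (the field protocol has
#' several secondary sessions per year; the model is annual). Sex codes are
#' case-insensitive `M`/`F`, with empty, `U` or `NA` meaning unknown; an
#' individual recorded with both sexes is a validation error. All
#' validation problems are itemized in a single error message.
#'
#' @param path CSV file path.
#' @param mapping named list giving the column names for `id`, `year`,
#'   `svl` and `sex` (defaults `id`, `year`, `svl_mm`, `sex`).
#' @param svl_window plausibility window for observed SVL (mm).
#' @param years optional declared year range; records outside it are
#'   validation errors.
#' @return A [capture_data()] object.
#' @export
read_capture_data <- function(path,
                              mapping = list(id = "id", year = "year",
                                             svl = "svl_mm", sex = "sex"),
                              svl_window = c(25, 90), years = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) stop("validation failed: file contains no records")
  missing_cols <- setdiff(unlist(mapping), names(raw))
  if (length(missing_cols))
    stop("validation failed: missing columns: ",
         paste(missing_cols, collapse = ", "))
  id <- trimws(raw[[mapping$id]])
  year <- suppressWarnings(as.integer(trimws(raw[[mapping$year]])))
  svl_chr <- trimws(raw[[mapping$svl]])
  svl <- suppressWarnings(as.numeric(svl_chr))
  sex_raw <- tolower(trimws(raw[[mapping$sex]]))

  problems <- character(0)
  bad_year <- which(is.na(year))
  if (length(bad_year))
    problems <- c(problems, sprintf("non-numeric year in rows: %s",
                                    paste(utils::head(bad_year, 10), collapse = ", ")))
  if (!is.null(years)) {
    out_year <- which(!is.na(year) & (year < years[1] | year > years[2]))
    if (length(out_year))
      problems <- c(problems, sprintf("year outside declared range in rows: %s",
                                      paste(utils::head(out_year, 10), collapse = ", ")))
  }
  bad_svl <- which(svl_chr != "" & is.na(svl))
  if (length(bad_svl))
    problems <- c(problems, sprintf("non-numeric SVL in rows: %s",
                                    paste(utils::head(bad_svl, 10), collapse = ", ")))
  known_codes <- c("m", "male", "f", "female", "u", "unknown", "", "na")
  bad_sex <- which(!sex_raw %in% known_codes)
  if (length(bad_sex))
    problems <- c(problems, sprintf("unknown sex codes in rows: %s (%s)",
                                    paste(utils::head(bad_sex, 10), collapse = ", "),
                                    paste(unique(sex_raw[utils::head(bad_sex, 10)]),
                                          collapse = ", ")))
  if (length(problems))
    stop("validation failed:\n  - ", paste(problems, collapse = "\n  - "))

  sex_norm <- rep(NA_character_, length(sex_raw))
  sex_norm[sex_raw %in% c("m", "male")] <- "male"
  sex_norm[sex_raw %in% c("f", "female")] <- "female"

  yrs <- sort(unique(year))
  occ <- match(year, yrs)
  ids <- unique(id)
  n <- length(ids); T <- length(yrs)
  y <- matrix(0L, n, T)
  svl_mat <- matrix(NA_real_, n, T)
  sex_vec <- rep(NA_character_, n)
  conflicts <- character(0)
  for (k in seq_along(id)) {
    i <- match(id[k], ids); t <- occ[k]
    if (y[i, t] == 0L) {          # first within-year record wins
      y[i, t] <- 1L
      svl_mat[i, t] <- svl[k]
    }
    if (!is.na(sex_norm[k])) {
      if (is.na(sex_vec[i])) sex_vec[i] <- sex_norm[k]
      else if (sex_vec[i] != sex_norm[k])
        conflicts <- c(conflicts, id[k])
    }
  }
  if (length(conflicts))
    stop("validation failed:\n  - conflicting sex records for individuals: ",
         paste(unique(conflicts), collapse = ", "))
  data <- capture_data(y = y, svl = svl_mat, sex = sex_vec, id = ids,
                       years = yrs, svl_window = svl_window)
  message(sprintf("read %d captures of %d individuals over %d occasions (%d male, %d female, %d unknown sex)",
                  sum(y), n, T, sum(sex_vec == "male", na.rm = TRUE),
                  sum(sex_vec == "female", na.rm = TRUE), sum(is.na(sex_vec))))
  data
}

#' Write a capture dataset as long-format CSV
#'
#' Inverse of [read_capture_data()]: one row per capture with columns
#' `id`, `year`, `svl_mm`, `sex` (`M`/`F`, empty when unknown). Reading the
#' file back reproduces all records and codes.
#'
#' @param data a [capture_data()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_capture_data <- function(data, path) {
  stopifnot(inherits(data, "capture_data"))
  rows <- which(data$y == 1L, arr.ind = TRUE)
  rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
  sx <- data$sex[rows[, 1]]
  df <- data.frame(id = data$id[rows[, 1]],
                   year = data$years[rows[, 2]],
                   svl_mm = data$svl[rows],
                   sex = ifelse(is.na(sx), "", ifelse(sx == "male", "M", "F")))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run manifest
#'
#' A reproducibility record for a fitted result: configuration snapshot,
#' seeds, package version, input-file checksums and timestamps. Every
#' artifact the pipeline writes can be traced back to one of these.
#'
#' @param config a [sampler_config()] (or any list-like config).
#' @param input_files character vector of input file paths (checksummed).
#' @param extra optional named list of extra fields.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, input_files = character(0), extra = list()) {
  sums <- if (length(input_files)) as.list(tools::md5sum(input_files)) else list()
  structure(c(list(package = "sizecmr",
                   version = as.character(utils::packageVersion("sizecmr")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed,
                   config = unclass(config),
                   input_md5 = sums),
              extra),
            class = "run_manifest")
}

#' Write a manifest as JSON
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write posterior draws to disk
#'
#' Columnar CSV with explicit chain and draw indices, one column per
#' monitored parameter.
#'
#' @param fit a `cmr_fit` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "cmr_fit"))
  pieces <- lapply(seq_along(fit$chains), function(ch) {
    d <- as.data.frame(fit$chains[[ch]])
    cbind(chain = ch, draw = seq_len(nrow(d)), d)
  })
  utils::write.csv(do.call(rbind, pieces), path, row.names = FALSE)
  invisible(path)
}
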