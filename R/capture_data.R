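#' Capture dataset
#'
#' Container for annual capture histories with observed body sizes. Rows are
#' individuals, columns are annual occasions. `svl` holds the observed
#' snout-to-vent length (mm) at each capture and `NA` where the individual
#' was not caught; `sex` is `"female"`, `"male"` or `NA` (unknown, to be
#' assigned by the model).
#'
#' @param y integer 0/1 detection matrix (individuals x occasions).
#' @param svl numeric matrix of observed SVL (mm), `NA` where `y == 0`.
#' @param sex character vector (`"female"`/`"male"`/`NA`), one per individual.
#' @param id optional individual identifiers (default row index).
#' @param years optional vector of calendar years, one per occasion.
#' @param svl_window plausibility window for observed SVL (mm).
#' @return An object of class `capture_data` with components `y`, `svl`,
#'   `sex`, `id`, `years`, `f` (first-capture occasion) and `last`
#'   (last-capture occasion).
#' @export
capture_data <- function(y, svl, sex, id = NULL, years = NULL,
                         svl_window = c(25, 90)) {
  y <- as.matrix(y)
  svl <- as.matrix(svl)
  storage.mode(y) <- "integer"
  n <- nrow(y); T <- ncol(y)
  if (!all(dim(svl) == dim(y))) stop("y and svl must have identical dimensions")
  if (length(sex) != n) stop("sex must have one entry per individual")
  if (!all(y %in% c(0L, 1L))) stop("y must be a 0/1 matrix")
  if (any(rowSums(y) == 0L)) stop("every individual must be captured at least once")
  sex <- tolower(as.character(sex))
  sex[sex %in% c("u", "unknown", "", "na")] <- NA_character_
  if (!all(sex %in% c("female", "male") | is.na(sex)))
    stop("sex must be 'female', 'male' or NA")
  if (any(!is.na(svl) & y == 0L))
    stop("SVL may only be observed on capture occasions (y == 1)")
  obs <- svl[!is.na(svl)]
  bad <- obs < svl_window[1] | obs > svl_window[2]
  if (any(bad))
    stop(sprintf("%d observed SVL values outside plausibility window [%g, %g] mm",
                 sum(bad), svl_window[1], svl_window[2]))
  f <- apply(y == 1L, 1L, which.max)
  last <- T + 1L - apply(y[, T:1, drop = FALSE] == 1L, 1L, which.max)
  if (is.null(id)) id <- seq_len(n)
  if (is.null(years)) years <- seq_len(T)
  structure(list(y = y, svl = svl, sex = sex, id = id, years = years,
                 f = as.integer(f), last = as.integer(last),
                 n = n, n_occasions = T),
            class = "capture_data")
}

#' @export
print.capture_data <- function(x, ...) {
  ns <- table(factor(x$sex, levels = c("male", "female")), useNA = "always")
  cat(sprintf(
    "Capture data: %d individuals, %d occasions, %d captures (%d males, %d females, %d unknown)\n",
    x$n, x$n_occasions, sum(x$y), ns[["male"]], ns[["female"]],
    sum(is.na(x$sex))))
  rng <- range(x$svl, na.rm = TRUE)
  cat(sprintf("Observed SVL: %.0f-%.0f mm\n", rng[1], rng[2]))
  invisible(x)
}

#' Number of captures in a dataset
#' @param data a [capture_data()] object.
#' @return Total number of detections.
#' @export
n_captures <- function(data) {
  stopifnot(inherits(data, "capture_data"))
  sum(data$y)
}

#' Covariate standardization constants
#'
#' Body size enters the survival and recapture linear predictors as a
#' standardized covariate, `(SVL - mean) / sd`, where the constants are the
#' mean and SD of all observed SVL values, computed once and then held fixed
#' (they are applied identically to latent imputed sizes).
#'
#' @param mean_svl,sd_svl constants in mm; `sd_svl > 0`.
#' @return An object of class `standardization`.
#' @export
standardization <- function(mean_svl, sd_svl) {
  if (!is.finite(sd_svl) || sd_svl <= 0) stop("sd_svl must be > 0")
  structure(list(mean_svl = mean_svl, sd_svl = sd_svl),
            class = "standardization")
}

#' Standardization constants from observed sizes
#' @param data a [capture_data()] object.
#' @return A [standardization()] object with the observed mean and SD.
#' @export
standardization_from_data <- function(data) {
  stopifnot(inherits(data, "capture_data"))
  obs <- data$svl[!is.na(data$svl)]
  standardization(mean(obs), stats::sd(obs))
}

#' Standardize a size
#' @param L size(s) in mm.
#' @param s a [standardization()] object.
#' @return Unitless covariate `(L - mean) / sd`.
#' @export
standardize <- function(L, s) {
  stopifnot(inherits(s, "standardization"))
  (L - s$mean_svl) / s$sd_svl
}

#' Invert the standardization
#' @param x unitless covariate value(s).
#' @param s a [standardization()] object.
#' @return Size in mm.
#' @export
unstandardize <- function(x, s) {
  stopifnot(inherits(s, "standardization"))
  x * s$sd_svl + s$mean_svl
}
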