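#' Expected life span under constant annual survival
#'
#' Assuming survival stays constant at `phi` once a reference size is
#' reached, remaining lifetime is geometric/exponential with annual rate
#' `-ln(phi)`, so the expected life span from that point is
#' \deqn{l_x = -1 / \ln \phi .}
#' Monotone increasing in `phi`; `phi = e^{-1}` gives exactly 1 year.
#'
#' @param phi annual survival probability in (0, 1). Vectorized.
#' @return Expected remaining life span in years.
#' @export
life_span <- function(phi) {
  if (any(phi <= 0 | phi >= 1)) stop("phi must lie in (0, 1)")
  -1 / log(phi)
}

#' Posterior life span after maturity
#'
#' For each posterior draw, sex-specific survival is evaluated at the
#' standardized size at maturity with year effects at zero, and converted
#' to an expected life span via [life_span()]. Summaries are the posterior
#' median and the equal-tailed 95% credible interval. Draws with survival
#' outside (0, 1) are excluded and counted (none arise from the logit
#' parameterisation, but the contract is explicit).
#'
#' @param fit a `cmr_fit` object (the fit monitors survival-at-maturity
#'   per draw as `phi_mat_f` / `phi_mat_m`).
#' @param thresholds unused here (thresholds were fixed at fit time);
#'   retained for interface clarity.
#' @return An object of class `life_span_estimate`: per-sex draws, medians,
#'   95% CRI and the count of excluded draws.
#' @export
life_span_posterior <- function(fit, thresholds = NULL) {
  stopifnot(inherits(fit, "cmr_fit"))
  d <- posterior_draws(fit)
  out <- list()
  for (s in c("f", "m")) {
    phi <- d[, paste0("phi_mat_", s)]
    ok <- phi > 0 & phi < 1
    ls <- life_span(phi[ok])
    out[[s]] <- list(draws = ls,
                     median = stats::median(ls),
                     lo95 = stats::quantile(ls, 0.025, names = FALSE),
                     hi95 = stats::quantile(ls, 0.975, names = FALSE),
                     n_excluded = sum(!ok))
  }
  structure(list(female = out$f, male = out$m), class = "life_span_estimate")
}

#' @export
print.life_span_estimate <- function(x, ...) {
  for (s in c("male", "female"))
    cat(sprintf("%s expected life span after maturity: %.2f years (95%% CRI %.2f-%.2f)\n",
                s, x[[s]]$median, x[[s]]$lo95, x[[s]]$hi95))
  invisible(x)
}

# shared: per-draw survival curve evaluation over a grid; internal
.curve_from_draws <- function(d, grid_std, sex01, what = c("phi", "p")) {
  what <- match.arg(what)
  ng <- length(grid_std)
  out <- matrix(NA_real_, nrow(d), ng)
  if (what == "phi") {
    for (k in seq_len(ng)) {
      x <- grid_std[k]
      lp <- d[, "alpha_phi"] + d[, "b_phi_sex"] * sex01 +
        d[, "b_phi_svl"] * x + d[, "b_phi_svl2"] * x^2 +
        d[, "b_phi_sex_svl"] * sex01 * x + d[, "b_phi_sex_svl2"] * sex01 * x^2
      out[, k] <- stats::plogis(lp)
    }
  } else {
    for (k in seq_len(ng)) {
      x <- grid_std[k]
      lp <- d[, "alpha_p"] + d[, "b_p_sex"] * sex01 +
        d[, "b_p_svl"] * x + d[, "b_p_sex_svl"] * sex01 * x
      out[, k] <- stats::plogis(lp)
    }
  }
  out
}

# mask excluded coefficients by the fitted model's effective inclusion
.masked_draws <- function(fit) {
  d <- posterior_draws(fit)
  cols <- c("b_phi_sex", "b_phi_svl", "b_phi_svl2", "b_phi_sex_svl",
            "b_phi_sex_svl2", "b_p_sex", "b_p_svl", "b_p_sex_svl")
  eff <- t(vapply(as.integer(d[, "mdl"]), decode_model_index, integer(8)))
  for (r in 1:8) d[, cols[r]] <- d[, cols[r]] * eff[, r]
  d
}

#' Size-dependent survival curve with credible band
#'
#' Posterior mean and equal-tailed 95% band of annual survival over a size
#' grid, per sex, with year effects at zero. Coefficients excluded from the
#' fitted model contribute nothing (they are masked by the per-draw
#' effective inclusion state).
#'
#' @param fit a `cmr_fit` object.
#' @param sizes size grid in mm (should lie within the observed range).
#' @return Tidy data frame: `svl_mm`, `sex`, `mean`, `lo95`, `hi95`.
#' @export
survival_vs_size <- function(fit, sizes = seq(35, 75, by = 2)) {
  stopifnot(inherits(fit, "cmr_fit"))
  d <- .masked_draws(fit)
  grid_std <- standardize(sizes, fit$std)
  rows <- list()
  for (s in 0:1) {
    cur <- .curve_from_draws(d, grid_std, s, "phi")
    rows[[s + 1]] <- data.frame(
      svl_mm = sizes,
      sex = ifelse(s == 1, "male", "female"),
      mean = colMeans(cur),
      lo95 = apply(cur, 2, stats::quantile, 0.025),
      hi95 = apply(cur, 2, stats::quantile, 0.975))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age-dependent survival curve via the age-by-size transformation
#'
#' Composes the growth map with the size-dependent survival curve: for each
#' posterior draw, age is converted to size along the sex-specific
#' population growth curve (hyper-level K and reference sizes of that
#' draw), the size is standardized, and survival is evaluated exactly as in
#' [survival_vs_size()]. For any fixed draw the composition is exact: sex
#' differences in the age curve can arise purely from growth differences
#' even where the size curves coincide.
#'
#' @param fit a `cmr_fit` object.
#' @param ages age grid in years (non-negative).
#' @param hatch_mean hatchling size (mm) anchoring the population curve.
#' @param T1,T2 growth reference ages (years).
#' @return Tidy data frame: `age_years`, `sex`, `mean`, `lo95`, `hi95`.
#' @export
survival_vs_age <- function(fit, ages = seq(0, 12, by = 0.5),
                            hatch_mean = 33, T1 = 0, T2 = 14) {
  stopifnot(inherits(fit, "cmr_fit"), all(ages >= 0))
  d <- .masked_draws(fit)
  rows <- list()
  for (s in 0:1) {
    suff <- if (s == 1) "m" else "f"
    K <- d[, paste0("K_", suff)]
    Linf <- d[, paste0("Linf_", suff)]
    cur <- matrix(NA_real_, nrow(d), length(ages))
    for (k in seq_along(ages)) {
      ed <- exp(-K * (ages[k] - T1))
      L <- hatch_mean * ed + Linf * (1 - ed)
      x <- standardize(L, fit$std)
      lp <- d[, "alpha_phi"] + d[, "b_phi_sex"] * s +
        d[, "b_phi_svl"] * x + d[, "b_phi_svl2"] * x^2 +
        d[, "b_phi_sex_svl"] * s * x + d[, "b_phi_sex_svl2"] * s * x^2
      cur[, k] <- stats::plogis(lp)
    }
    rows[[s + 1]] <- data.frame(
      age_years = ages,
      sex = ifelse(s == 1, "male", "female"),
      mean = colMeans(cur),
      lo95 = apply(cur, 2, stats::quantile, 0.025),
      hi95 = apply(cur, 2, stats::quantile, 0.975))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annual survival and recapture series
#'
#' Per-year posterior summaries of survival and recapture probabilities at
#' mean covariate values (standardized size zero, sexes averaged with the
#' posterior sex ratio), obtained by pushing each year's random effect
#' through the inverse logit draw by draw.
#'
#' @param fit a `cmr_fit` object.
#' @return Tidy data frame: `occasion`, `series` ("phi" or "p"), `mean`,
#'   `lo95`, `hi95`.
#' @export
annual_series <- function(fit) {
  stopifnot(inherits(fit, "cmr_fit"))
  d <- .masked_draws(fit)
  T <- fit$n_occasions
  psi <- d[, "psi"]
  rows <- list()
  for (t in seq_len(T - 1)) {
    lp_f <- d[, "alpha_phi"] + d[, paste0("eps_phi[", t, "]")]
    lp_m <- lp_f + d[, "b_phi_sex"]
    phi <- (1 - psi) * stats::plogis(lp_f) + psi * stats::plogis(lp_m)
    rows[[length(rows) + 1]] <- data.frame(
      occasion = t, series = "phi", mean = mean(phi),
      lo95 = stats::quantile(phi, 0.025, names = FALSE),
      hi95 = stats::quantile(phi, 0.975, names = FALSE))
    lq_f <- d[, "alpha_p"] + d[, paste0("eps_p[", t + 1, "]")]
    lq_m <- lq_f + d[, "b_p_sex"]
    p <- (1 - psi) * stats::plogis(lq_f) + psi * stats::plogis(lq_m)
    rows[[length(rows) + 1]] <- data.frame(
      occasion = t + 1, series = "p", mean = mean(p),
      lo95 = stats::quantile(p, 0.025, names = FALSE),
      hi95 = stats::quantile(p, 0.975, names = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
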