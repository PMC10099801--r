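#' Names of the selectable predictors
#'
#' Eight predictors are subject to selection: five on survival (sex, SVL,
#' SVL^2, sex x SVL, sex x SVL^2) and three on recapture (sex, SVL,
#' sex x SVL). Intercepts and year effects are always in the model.
#'
#' @return Character vector of length 8, in the canonical order used by all
#'   inclusion vectors in the package.
#' @export
predictor_names <- function() {
  c("phi_sex", "phi_svl", "phi_svl2", "phi_sex_svl", "phi_sex_svl2",
    "p_sex", "p_svl", "p_sex_svl")
}

#' Encode an inclusion vector as a model index
#'
#' The model visited at an MCMC iteration is encoded as
#' \deqn{mdl = 1 + \sum_{r=1}^{P} 2^r g_r,} a bijection between binary
#' inclusion vectors and integers; converting back to binary recovers the
#' status of each inclusion indicator.
#'
#' @param g binary vector (0/1) of inclusion indicators, r = 1..P.
#' @return Integer model index.
#' @export
encode_model_index <- function(g) {
  if (!all(g %in% c(0, 1))) stop("g must be a binary vector")
  as.integer(1 + sum(2^(seq_along(g)) * g))
}

#' Decode a model index back to the inclusion vector
#'
#' @param mdl integer model index as produced by [encode_model_index()].
#' @param P number of inclusion indicators (default 8).
#' @return Binary vector `g` of length `P`.
#' @export
decode_model_index <- function(mdl, P = 8L) {
  x <- mdl - 1L
  g <- integer(P)
  for (r in seq_len(P)) g[r] <- as.integer((x %/% 2^r) %% 2)
  g
}

#' Apply the marginality (hierarchy) constraint to an inclusion vector
#'
#' The effective contribution of a term drops out of the likelihood when a
#' parent term is off: the quadratic SVL term requires the linear term;
#' sex x SVL requires sex and SVL; sex x SVL^2 requires sex, SVL and SVL^2;
#' on recapture, sex x SVL requires sex and SVL.
#'
#' @param g binary inclusion vector of length 8 (see [predictor_names()]).
#' @return Binary vector of *effective* inclusions, same length.
#' @export
effective_inclusion <- function(g) {
  stopifnot(length(g) == 8L)
  e <- as.integer(g)
  e[3] <- e[3] * e[2]                 # svl2 needs svl
  e[4] <- e[4] * e[1] * e[2]          # sex:svl needs sex, svl
  e[5] <- e[5] * e[1] * e[2] * e[3]   # sex:svl2 needs sex, svl, svl2
  e[8] <- e[8] * e[6] * e[7]          # p sex:svl needs p sex, p svl
  e
}

#' Enumerate the admissible model space
#'
#' All effective models compatible with the marginality constraint: 10
#' survival sub-models times 5 recapture sub-models.
#'
#' @return Matrix with one admissible effective inclusion vector per row,
#'   with column names from [predictor_names()].
#' @export
admissible_models <- function() {
  grid <- as.matrix(expand.grid(rep(list(0:1), 8)))
  eff <- t(apply(grid, 1, effective_inclusion))
  eff <- unique(eff)
  colnames(eff) <- predictor_names()
  eff[order(rowSums(eff), apply(eff, 1, function(r) encode_model_index(r))), ,
      drop = FALSE]
}

#' Human-readable model notation
#'
#' @param g effective inclusion vector of length 8.
#' @return A string such as `"phi(sex + svl), p(sex + svl)"`.
#' @export
model_notation <- function(g) {
  terms_phi <- c("sex", "svl", "svl2", "sex:svl", "sex:svl2")[g[1:5] == 1]
  terms_p <- c("sex", "svl", "sex:svl")[g[6:8] == 1]
  phi <- if (length(terms_phi)) paste(terms_phi, collapse = " + ") else "."
  p <- if (length(terms_p)) paste(terms_p, collapse = " + ") else "."
  sprintf("phi(%s), p(%s)", phi, p)
}

#' Select models from GVS output
#'
#' Two standard selection rules are reported: the median-probability model
#' (all predictors with marginal inclusion probability strictly above 0.5)
#' and the maximum-a-posteriori model (largest posterior model probability;
#' ties broken in favour of the model with fewer predictors).
#'
#' @param inclusion_probs named numeric vector of length 8 of marginal
#'   inclusion probabilities (order of [predictor_names()]).
#' @param model_probs optional named numeric vector of posterior model
#'   probabilities; names are model indices (see [encode_model_index()]).
#' @return List with `median_model` (effective inclusion vector),
#'   `median_notation`, and when model probabilities are supplied
#'   `best_model`, `best_notation`, `best_prob`.
#' @export
select_model <- function(inclusion_probs, model_probs = NULL) {
  stopifnot(length(inclusion_probs) == 8L)
  med <- effective_inclusion(as.integer(inclusion_probs > 0.5))
  out <- list(median_model = med, median_notation = model_notation(med))
  if (!is.null(model_probs) && length(model_probs)) {
    idx <- as.integer(names(model_probs))
    sizes <- vapply(idx, function(m) sum(decode_model_index(m)), numeric(1))
    ord <- order(-model_probs, sizes)
    top <- idx[ord[1]]
    g <- decode_model_index(top)
    out$best_model <- g
    out$best_notation <- model_notation(g)
    out$best_prob <- unname(model_probs[ord[1]])
  }
  out
}
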