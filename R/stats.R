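# Decoy-based statistical validation of target hits under Bonferroni
# correction.

#' Bonferroni-corrected per-test critical value
#'
#' @param alpha_whole family-wise error rate, in (0, 1] (default 0.05).
#' @param K number of target peptide entries in the composite database.
#' @return `alpha_whole / K`.
#' @export
bonferroni_alpha <- function(alpha_whole = 0.05, K) {
  if (length(K) != 1L || is.na(K) || K < 1) stop("K must be a positive count")
  stopifnot(alpha_whole > 0)
  alpha_whole / K
}

#' Empirical p-value of a target score against a decoy score list
#'
#' Add-one (Laplace) smoothed right-tail estimate
#' `p = (1 + #\{d >= s\}) / (1 + N)`, so p is never 0 and is defined
#' (conservatively 1) for an empty decoy list. Decoy ties with the target
#' score count against the target.
#'
#' @param s target hit score (vectorized).
#' @param decoy_scores numeric vector of decoy scores for the same spectrum.
#' @return p-value(s) in (0, 1].
#' @export
empirical_pvalue <- function(s, decoy_scores) {
  n <- length(decoy_scores)
  vapply(s, function(si) (1 + sum(decoy_scores >= si)) / (1 + n), numeric(1))
}

#' Gumbel right-tail p-value from decoy scores
#'
#' Fits a Gumbel (type-I extreme value) distribution to the spectrum's
#' decoy scores by the method of moments (`beta = sd * sqrt(6) / pi`,
#' `mu = mean - gamma * beta` with the Euler-Mascheroni constant) and
#' evaluates `P(S >= s) = 1 - exp(-exp(-(s - mu)/beta))` analytically. With
#' fewer than 3 decoys, or degenerate (constant) scores, it falls back to
#' the smoothed empirical estimate.
#'
#' The parametric tail is what makes rejection below a Bonferroni-corrected
#' alpha of ~5e-9 reachable: an empirical estimate is bounded below by
#' 1/(N+1) for a decoy list of size N.
#'
#' @inheritParams empirical_pvalue
#' @return p-value(s) in (0, 1].
#' @export
gumbel_pvalue <- function(s, decoy_scores) {
  n <- length(decoy_scores)
  sdv <- stats::sd(decoy_scores)
  if (n < 3L || !is.finite(sdv) || sdv == 0)
    return(empirical_pvalue(s, decoy_scores))
  beta <- sdv * sqrt(6) / pi
  mu <- mean(decoy_scores) - 0.57721566490153286 * beta
  z <- (s - mu) / beta
  # -expm1(-exp(-z)) is the survival function, stable for large z
  p <- -expm1(-exp(-z))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Significance configuration
#'
#' @param alpha_whole family-wise error rate (default 0.05).
#' @param K number of target peptide entries.
#' @param pvalue_mode `"gumbel"` (default) or `"empirical"`.
#' @return a `significance_config` with derived per-test `alpha`.
#' @export
significance_config <- function(alpha_whole = 0.05, K,
                                pvalue_mode = c("gumbel", "empirical")) {
  pvalue_mode <- match.arg(pvalue_mode)
  structure(list(alpha_whole = alpha_whole, K = K,
                 alpha = bonferroni_alpha(alpha_whole, K),
                 pvalue_mode = pvalue_mode),
            class = "significance_config")
}

#' Annotate target hits with p-values and keep the significant ones
#'
#' Every target hit gets a p-value from the spectrum's decoy score
#' distribution; hits with `p < alpha` (strict) survive. Input order is
#' preserved.
#'
#' @param target_hits target hit data.frame ([search_spectrum()]).
#' @param decoy_scores numeric vector of decoy scores for the same spectrum.
#' @param config a [significance_config()].
#' @return list with `annotated` (all target hits, `p_value` filled) and
#'   `significant` (the surviving subset).
#' @export
filter_significant <- function(target_hits, decoy_scores, config) {
  pfun <- switch(config$pvalue_mode,
                 gumbel = gumbel_pvalue, empirical = empirical_pvalue)
  if (nrow(target_hits) > 0L)
    target_hits$p_value <- pfun(target_hits$score, decoy_scores)
  list(annotated = target_hits,
       significant = target_hits[target_hits$p_value < config$alpha, ,
                                 drop = FALSE])
}
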