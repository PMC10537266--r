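#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-gene residual variances toward a common prior fitted across
#' genes, stabilising inference when per-gene degrees of freedom are small.
#' The residual variances are modelled as scaled chi-square draws around a
#' scaled-inverse-chi-square prior with `df_prior` degrees of freedom and
#' scale `var_prior`; the hyperparameters are estimated by matching moments
#' of the log residual variances (digamma/trigamma corrections, with the
#' trigamma equation inverted by Newton iteration). The posterior variance
#' for each gene is the degrees-of-freedom-weighted combination
#' `(df_prior * var_prior + df * s2) / (df_prior + df)`.
#'
#' When the observed variances carry no excess spread beyond chi-square
#' sampling noise the prior df is infinite and all posterior variances
#' equal the common prior scale; when the variances are (numerically)
#' identical they are returned unchanged and a warning notes that the
#' distribution is degenerate.
#'
#' @param s2 Numeric vector of residual variances (>= 10 genes).
#' @param df Residual degrees of freedom, recycled to the length of `s2`.
#' @return List: `var_post` (shrunken variances), `df_prior`, `var_prior`.
#' @export
moderate_variances <- function(s2, df) {
  if (length(s2) < 10)
    stop("variance moderation needs at least 10 genes")
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!all(ok)) stop("residual variances and df must be positive and finite")
  z <- log(s2)
  if (stats::var(z) < 1e-12) {
    warning("residual variance distribution is degenerate; ",
            "moderation skipped")
    return(list(var_post = s2, df_prior = Inf, var_prior = mean(s2)))
  }
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    var_post <- (df_prior * var_prior + df * s2) / (df_prior + df)
  } else {
    # no excess spread beyond chi-square noise: infinite prior df, and the
    # common scale is best estimated by the plain mean of the variances
    df_prior <- Inf
    var_prior <- mean(s2)
    var_post <- rep(var_prior, length(s2))
  }
  list(var_post = var_post, df_prior = df_prior, var_prior = var_prior)
}

# solve trigamma(x) = y for x > 0 by Newton iteration on x
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (x <= 0) x <- 1e-8
    if (abs(dif) < 1e-10 * x) break
  }
  x
}
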