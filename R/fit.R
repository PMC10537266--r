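#' Build the per-virus differential-expression design
#'
#' Restricts the libraries to the projects in which the virus was called
#' present at least once, then assembles the fixed-effect design and the
#' random-intercept grouping according to the term-dropping rules:
#'
#' * the sex term (and its interaction with virus) enters only when the
#'   restricted libraries contain both sexes *and* the virus was called in
#'   both sexes; otherwise the model reduces to the virus term alone;
#' * the grouping label concatenates the stratum columns (`project`,
#'   `genotype`, `tissue`, and any columns named in `strata`) that have
#'   more than one level among the restricted libraries; a stratum with a
#'   single level is dropped from the label, and when the whole label has a
#'   single level the random intercept is omitted (plain fixed-effects
#'   fit).
#'
#' Uninfected females are the reference condition. Libraries whose sex is
#' neither `"male"` nor `"female"` are excluded when the sex term is used.
#'
#' @param meta Metadata data.frame with `library_id`, `project` and the
#'   stratum columns; sex is taken from `sex_verified` if present, else
#'   `sex`.
#' @param calls An `infection_calls` object or logical matrix.
#' @param virus Virus label (a column of the call matrix).
#' @param strata Extra metadata columns to fold into the grouping label
#'   (e.g. treatment); defaults to `c("genotype", "tissue", "treatment")`
#'   intersected with the available columns.
#' @return List of class `de_design`: `virus`, `libraries`, `X` (design
#'   matrix with columns from `(Intercept)`, `sexmale`, `virus`,
#'   `sexmale:virus`), `terms` (character), `group` (factor or `NULL`),
#'   `infected` (logical), `sex` (character), `meta` (restricted rows).
#' @export
build_design <- function(meta, calls, virus,
                         strata = c("genotype", "tissue", "treatment")) {
  present <- if (inherits(calls, "infection_calls")) calls$present else
    as.matrix(calls)
  if (!virus %in% colnames(present))
    stop("virus '", virus, "' is not a column of the call matrix")
  if (!any(present[, virus]))
    stop("virus '", virus, "' was never called present")
  meta <- .align_meta(meta, rownames(present))
  sex_col <- if ("sex_verified" %in% names(meta)) "sex_verified" else "sex"
  if (!sex_col %in% names(meta))
    stop("metadata needs a 'sex' or 'sex_verified' column")

  pos_projects <- unique(meta$project[present[, virus]])
  keep <- meta$project %in% pos_projects
  metak <- meta[keep, , drop = FALSE]
  infected <- present[keep, virus]
  sex <- metak[[sex_col]]

  sexes_called <- unique(sex[infected])
  both_sexes <- all(c("male", "female") %in% sex) &&
    all(c("male", "female") %in% sexes_called)
  if (both_sexes) {
    ok <- sex %in% c("male", "female")
    metak <- metak[ok, , drop = FALSE]
    infected <- infected[ok]
    sex <- sex[ok]
    sexf <- factor(sex, levels = c("female", "male"))
    X <- cbind("(Intercept)" = 1,
               sexmale = as.numeric(sexf == "male"),
               virus = as.numeric(infected))
    X <- cbind(X, "sexmale:virus" = X[, "sexmale"] * X[, "virus"])
    terms <- c("sex", "virus", "sex:virus")
  } else {
    X <- cbind("(Intercept)" = 1, virus = as.numeric(infected))
    terms <- "virus"
  }
  rownames(X) <- metak$library_id

  gcols <- intersect(c("project", strata), names(metak))
  gcols <- gcols[vapply(gcols, function(cl)
    length(unique(metak[[cl]])) > 1L, logical(1))]
  group <- if (length(gcols)) {
    g <- interaction(metak[gcols], drop = TRUE, sep = "_")
    if (nlevels(g) > 1L) g else NULL
  } else NULL

  structure(list(virus = virus, libraries = metak$library_id, X = X,
                 terms = terms, group = group, infected = infected,
                 sex = sex, meta = metak),
            class = "de_design")
}

#' @export
print.de_design <- function(x, ...) {
  cat(sprintf("de_design for %s: %d libraries, terms {%s}, %s\n",
              x$virus, nrow(x$X), paste(x$terms, collapse = ", "),
              if (is.null(x$group)) "no random intercept" else
                sprintf("random intercept over %d groups",
                        nlevels(x$group))))
  invisible(x)
}

## ---- internal REML machinery -------------------------------------------

# One-off spectral preparation shared by all genes fitted on the same
# design: eigen-decompose ZZ' (Z = group indicator matrix) so the marginal
# covariance sigma2 * (I + lambda ZZ') is diagonal after rotation.
.prep_mixed <- function(X, group) {
  X <- as.matrix(X)
  if (is.null(group) || nlevels(group) < 2L)
    return(list(mixed = FALSE, X = X, n = nrow(X), p = ncol(X)))
  Z <- stats::model.matrix(~ 0 + group)
  e <- eigen(tcrossprod(Z), symmetric = TRUE)
  d <- pmax(e$values, 0)
  Q <- e$vectors
  list(mixed = TRUE, Q = Q, d = d, X = crossprod(Q, X),
       n = nrow(X), p = ncol(X))
}

# -2 REML log-likelihood (up to a constant) in the rotated basis, as a
# function of the variance ratio lambda = sigma2_g / sigma2_e.
.reml_neg2ll <- function(loglam, Xt, d, yt) {
  lam <- exp(loglam)
  w <- 1 / (1 + lam * d)
  fit <- stats::lm.wfit(Xt, yt, w)
  rss <- sum(w * fit$residuals^2)
  n <- length(yt); p <- ncol(Xt)
  XtWX <- crossprod(Xt * w, Xt)
  (n - p) * log(rss / (n - p)) - sum(log(w)) +
    as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
}

# unprofiled -2 REML criterion in theta = (sigma2_e, sigma2_g); used for the
# numeric Hessian feeding the Satterthwaite df
.reml_neg2ll_theta <- function(theta, Xt, d, yt) {
  v <- theta[1] + theta[2] * d
  if (any(v <= 0)) return(Inf)
  w <- 1 / v
  fit <- stats::lm.wfit(Xt, yt, w)
  rss <- sum(w * fit$residuals^2)
  XtWX <- crossprod(Xt * w, Xt)
  sum(log(v)) + as.numeric(determinant(XtWX, logarithm = TRUE)$modulus) + rss
}

# Satterthwaite-type df for each coefficient: df_j = 2 f_j^2 / var(f_j),
# with f_j(theta) = [ (X' V(theta)^-1 X)^-1 ]_jj and var(f_j) from the
# delta method using the inverse numeric REML Hessian.
.satterthwaite_df <- function(theta, Xt, d, yt, fallback_df) {
  p <- ncol(Xt)
  fj <- function(th) {
    v <- th[1] + th[2] * d
    diag(solve(crossprod(Xt / v, Xt)))
  }
  h <- pmax(abs(theta) * 1e-4, 1e-10)
  G <- matrix(0, 2, p)
  for (k in 1:2) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + h[k]; tm[k] <- max(tm[k] - h[k], 0)
    G[k, ] <- (fj(tp) - fj(tm)) / (tp[k] - tm[k])
  }
  H <- matrix(0, 2, 2)
  f0 <- .reml_neg2ll_theta(theta, Xt, d, yt)
  for (k in 1:2) for (l in 1:k) {
    tpp <- theta; tpp[k] <- tpp[k] + h[k]; tpp[l] <- tpp[l] + h[l]
    tp1 <- theta; tp1[k] <- tp1[k] + h[k]
    tp2 <- theta; tp2[l] <- tp2[l] + h[l]
    H[k, l] <- H[l, k] <-
      (.reml_neg2ll_theta(tpp, Xt, d, yt) -
         .reml_neg2ll_theta(tp1, Xt, d, yt) -
         .reml_neg2ll_theta(tp2, Xt, d, yt) + f0) / (h[k] * h[l])
  }
  covth <- tryCatch(2 * solve(H), error = function(e) NULL)
  f <- fj(theta)
  if (is.null(covth)) return(rep(fallback_df, p))
  df <- vapply(seq_len(p), function(j) {
    vv <- drop(t(G[, j]) %*% covth %*% G[, j])
    if (!is.finite(vv) || vv <= 0) return(fallback_df)
    2 * f[j]^2 / vv
  }, numeric(1))
  pmin(pmax(df, 1), fallback_df)
}

#' Fit the per-gene expression model
#'
#' Fits one gene's log2-CPM expression on the fixed-effect design with an
#' optional random intercept. With a grouping factor of two or more levels
#' the model is a linear mixed model with a single variance component,
#' estimated by REML: the group indicator cross-product is diagonalised
#' once, the variance ratio is profiled by 1-D optimisation, and
#' Satterthwaite-type degrees of freedom are obtained from a numeric
#' Hessian of the REML criterion. Without grouping (or when the REML
#' estimate of the group variance is zero) the fit reduces to ordinary
#' least squares with residual degrees of freedom.
#'
#' @param expr_row Numeric expression vector (one gene, one value per
#'   library, log2 scale).
#' @param design Design matrix (libraries x coefficients) or a `de_design`
#'   object from [build_design()].
#' @param random_group Factor of group labels (ignored when `design` is a
#'   `de_design`, which carries its own); `NULL` for plain OLS.
#' @return data.frame with one row per coefficient: `coefficient`, `logFC`
#'   (estimate), `se`, `stat`, `df`, `p`; attributes `sigma2` (residual
#'   variance), `df_residual`, `lambda` (REML variance ratio) and
#'   `converged`.
#' @export
fit_gene_model <- function(expr_row, design, random_group = NULL) {
  if (inherits(design, "de_design")) {
    random_group <- design$group
    design <- design$X
  }
  prep <- .prep_mixed(design, random_group)
  yt <- if (prep$mixed) drop(crossprod(prep$Q, expr_row)) else expr_row
  .fit_gene_prepared(yt, prep)
}

# core fit on a pre-rotated response; shared by fit_gene_model and run_de
.fit_gene_prepared <- function(yt, prep) {
  Xt <- prep$X
  n <- prep$n; p <- prep$p
  if (n <= p) stop("more coefficients than libraries")
  coef_names <- colnames(Xt)
  ols <- function() {
    fit <- stats::lm.fit(Xt, yt)
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - p)
    XtXinv <- tryCatch(solve(crossprod(Xt)), error = function(e) NULL)
    if (is.null(XtXinv)) return(NULL)
    se <- sqrt(s2 * diag(XtXinv))
    list(beta = fit$coefficients, se = se, df = rep(n - p, p), s2 = s2,
         lambda = 0)
  }
  res <- NULL
  converged <- TRUE
  if (prep$mixed) {
    d <- prep$d
    opt <- tryCatch(
      stats::optimize(.reml_neg2ll, c(-12, 12), Xt = Xt, d = d, yt = yt),
      error = function(e) NULL)
    if (is.null(opt)) {
      converged <- FALSE
    } else {
      at_zero <- .reml_neg2ll(-30, Xt, d, yt)
      if (at_zero <= opt$objective + 1e-8) {
        res <- ols()                      # boundary: group variance ~ 0
      } else {
        lam <- exp(opt$minimum)
        w <- 1 / (1 + lam * d)
        fit <- stats::lm.wfit(Xt, yt, w)
        rss <- sum(w * fit$residuals^2)
        s2 <- rss / (n - p)
        XtWXinv <- tryCatch(solve(crossprod(Xt * w, Xt)),
                            error = function(e) NULL)
        if (is.null(XtWXinv)) {
          converged <- FALSE
        } else {
          se <- sqrt(s2 * diag(XtWXinv))
          df <- .satterthwaite_df(c(s2, lam * s2), Xt, d, yt,
                                  fallback_df = n - p)
          res <- list(beta = fit$coefficients, se = se, df = df, s2 = s2,
                      lambda = lam)
        }
      }
    }
  }
  if (is.null(res)) res <- ols()          # OLS path or mixed-fit fallback
  if (is.null(res)) stop("design is rank deficient for this gene")
  stat <- res$beta / res$se
  out <- data.frame(coefficient = coef_names, logFC = unname(res$beta),
                    se = unname(res$se), stat = unname(stat),
                    df = unname(res$df),
                    p = unname(2 * stats::pt(-abs(stat), res$df)),
                    stringsAsFactors = FALSE)
  attr(out, "sigma2") <- res$s2
  attr(out, "df_residual") <- n - p
  attr(out, "lambda") <- res$lambda
  attr(out, "converged") <- converged
  out
}
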