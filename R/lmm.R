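# Mixed-model engine: REML variance components via one eigendecomposition of
# the GRM, then per-variant generalized least squares with the components
# held fixed (the single-eigendecomposition trick used by fast LMM-GWAS
# software). All scans funnel through gls_pair_scan().

# profile the restricted likelihood over the variance ratio on rotated data:
# yt = U'y, Xt = U'X, d = GRM eigenvalues. Returns the REML optimum.
reml_profile <- function(yt, Xt, d, max_h2 = 0.9999) {
  n <- length(yt)
  p <- ncol(Xt)
  at <- function(h2) {
    gamma <- h2 / (1 - h2)
    w <- 1 / (gamma * d + 1)
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    beta <- solve(XtWX, crossprod(XtW, yt))
    r <- yt - drop(Xt %*% beta)
    rss <- sum(w * r^2)
    sigma_e2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma_e2) + (n - p) +
                    sum(log(gamma * d + 1)) +
                    as.numeric(determinant(XtWX, logarithm = TRUE)$modulus))
    list(ll = ll, sigma_e2 = sigma_e2, gamma = gamma, h2 = h2)
  }
  opt <- optimize(function(h) at(h)$ll, c(0, max_h2), maximum = TRUE,
                  tol = 1e-9)
  at0 <- at(0)  # the sigma_g2 = 0 boundary beats a flat interior
  if (at0$ll >= opt$objective) at0 else at(opt$maximum)
}

# build a fixed-effects design matrix with intercept from NULL / data frame /
# matrix input
build_design <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (is.data.frame(X)) {
    X <- as.data.frame(X)
    chr_cols <- vapply(X, is.character, logical(1))
    X[chr_cols] <- lapply(X[chr_cols], factor)
    # single-level factors carry no contrast; drop them (constant covariate)
    const_fct <- vapply(X, function(c) is.factor(c) &&
                          nlevels(droplevels(c)) < 2, logical(1))
    X <- X[!const_fct]
    if (!ncol(X)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
    return(stats::model.matrix(~ ., data = droplevels(X)))
  }
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(c) all(c == c[1])))) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  X
}

# drop collinear columns (keeping the earliest), warning with their names
drop_collinear <- function(X, context = "design") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    warn(sprintf("dropping %d collinear column(s) from %s: %s",
                 length(drop), context,
                 paste(colnames(X)[drop], collapse = ", ")))
    X <- X[, -drop, drop = FALSE]
  }
  X
}

#' Fit the null linear mixed model by REML
#'
#' Fits y = X beta + g + e with g ~ N(0, G sigma_g^2), e ~ N(0, sigma_e^2 I)
#' by restricted maximum likelihood. A single eigendecomposition of the
#' (complete-case subsetted) GRM diagonalizes the covariance, so the
#' restricted likelihood is profiled over the variance ratio in one
#' univariate optimization.
#'
#' @param y Numeric phenotype vector (NAs allowed; complete-case subsetting
#'   of y, X and GRM is applied).
#' @param X Covariates: `NULL` (intercept only), a data frame (factors
#'   expanded via `model.matrix`), or a numeric matrix.
#' @param grm A `grm` whose samples align with `y` (same order), or `NULL`
#'   for a pure fixed-effects model (sigma_g^2 fixed at 0).
#' @param max_h2 Upper bound of the heritability search interval.
#' @return An `lmm_fit` with elements `sigma_g2`, `sigma_e2`, `h2`,
#'   `reml_loglik`, `n`, plus cached rotation objects reused by
#'   [assoc_scan()]. Has [tidy()] and [glance()] methods.
#' @export
fit_null_lmm <- function(y, X = NULL, grm = NULL, max_h2 = 0.9999) {
  n_all <- length(y)
  Xm <- build_design(X, n_all)
  if (nrow(Xm) != n_all) abort("`X` and `y` have incompatible dimensions")
  keep <- complete.cases(y, Xm)
  y <- y[keep]
  Xm <- drop_collinear(Xm[keep, , drop = FALSE], "covariates")
  n <- length(y)
  p <- ncol(Xm)
  if (n <= p + 1) abort("too few complete observations to fit the model")

  if (is.null(grm)) {
    qrX <- qr(Xm)
    r <- qr.resid(qrX, y)
    rss <- sum(r^2)
    sigma_e2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma_e2) + (n - p) +
                    as.numeric(determinant(crossprod(Xm), logarithm = TRUE)$modulus))
    fit <- list(sigma_g2 = 0, sigma_e2 = sigma_e2,
                h2 = 0, reml_loglik = as.numeric(ll),
                n = n, p = p, keep = keep, X = Xm, y = y,
                eigen = NULL, converged = TRUE)
    return(structure(fit, class = "lmm_fit"))
  }

  stopifnot(inherits(grm, "grm"))
  if (length(grm$sample_ids) != n_all) {
    abort("`grm` and `y` have incompatible dimensions")
  }
  G <- grm$values[keep, keep, drop = FALSE]
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    abort("GRM is not positive semidefinite after subsetting")
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, Xm)

  best <- reml_profile(yt, Xt, d, max_h2 = max_h2)
  sigma_e2 <- best$sigma_e2
  sigma_g2 <- best$gamma * sigma_e2
  fit <- list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
              h2 = sigma_g2 / (sigma_g2 + sigma_e2),
              reml_loglik = best$ll,
              n = n, p = p, keep = keep, X = Xm, y = y,
              eigen = list(d = d, U = U), converged = TRUE)
  structure(fit, class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> n = ", x$n, ", sigma_g2 = ", signif(x$sigma_g2, 4),
      ", sigma_e2 = ", signif(x$sigma_e2, 4),
      ", h2 = ", round(x$h2, 4),
      ", REML loglik = ", round(x$reml_loglik, 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lmm_fit <- function(x, ...) {
  tibble(term = c("sigma_g2", "sigma_e2", "h2"),
         estimate = c(x$sigma_g2, x$sigma_e2, x$h2))
}

#' @exportS3Method generics::glance
glance.lmm_fit <- function(x, ...) {
  tibble(h2 = x$h2, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
         reml_loglik = x$reml_loglik, nobs = x$n, converged = x$converged)
}
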