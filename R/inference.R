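#' Box-Cox transformation
#'
#' `(y^lambda - 1) / lambda` for `lambda != 0`, `log(y)` for `lambda = 0`;
#' continuous in lambda and monotone in y, so ranks are preserved.
#'
#' @param y Positive values.
#' @param lambda Power parameter.
#' @return Transformed values.
#' @export
boxcox_transform <- function(y, lambda) {
  if (any(y <= 0)) stop("Box-Cox requires positive values")
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

#' Box-Cox power estimated by profile likelihood
#'
#' The lambda maximising the profile log-likelihood of the normal linear
#' model on the transformed response over a grid (computed via
#' [MASS::boxcox()]). With no predictors the model is intercept-only.
#'
#' @param y Positive response values.
#' @param x Optional data frame/matrix of predictors.
#' @param grid Candidate lambdas (default `seq(-2, 2, 0.01)`).
#' @return The maximising lambda.
#' @export
boxcox_lambda <- function(y, x = NULL, grid = seq(-2, 2, by = 0.01)) {
  if (any(y <= 0)) stop("Box-Cox requires positive values")
  d <- if (is.null(x)) data.frame(.y = y) else {
    d <- as.data.frame(x); d$.y <- y; d
  }
  rhs <- if (is.null(x)) "1" else paste(setdiff(names(d), ".y"),
                                        collapse = " + ")
  # keep y and qr on the fit so boxcox need not re-evaluate the call
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d,
                   y = TRUE, qr = TRUE)
  prof <- MASS::boxcox(fit, lambda = grid, plotit = FALSE)
  prof$x[which.max(prof$y)]
}

#' Z-score the columns of a predictor table
#'
#' @param x Data frame or matrix of numeric predictors.
#' @return A data frame with each column centred to mean 0 and scaled to
#'   unit standard deviation.
#' @export
standardize <- function(x) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    s <- stats::sd(x[[j]])
    if (!is.finite(s) || s == 0) stop("constant column: ", names(x)[j])
    x[[j]] <- (x[[j]] - mean(x[[j]])) / s
  }
  x
}

#' Ordinary least-squares fit with information-criterion bookkeeping
#'
#' Wraps `lm`, recording the Gaussian log-likelihood, the parameter count
#' `k` (intercept + slopes + error variance, so a null model has k = 2), R^2
#' and the overall F statistic, as needed for AICc model comparison.
#'
#' @param data Data frame holding response and predictors.
#' @param response Response column name.
#' @param predictors Character vector of predictor names (may be empty for
#'   the intercept-only null model).
#' @param label Model label (defaults to `"null"` or the predictor names).
#' @return A list of class `ols_fit`: `label`, `predictors`, `fit` (the lm),
#'   `k`, `n`, `loglik`, `r2`, `fstat`, `coefficients` (estimate, se).
#' @export
fit_ols <- function(data, response, predictors = character(), label = NULL) {
  rhs <- if (length(predictors) == 0) "1"
         else paste(predictors, collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(f, data = data)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design matrix")
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit)) + 1  # + error variance
  if (n <= k) stop("more parameters than observations")
  sm <- summary(fit)
  structure(list(
    label = if (is.null(label)) {
      if (length(predictors) == 0) "null" else paste(predictors,
                                                     collapse = " + ")
    } else label,
    predictors = predictors, fit = fit, k = k, n = n,
    loglik = as.numeric(stats::logLik(fit)),
    r2 = sm$r.squared,
    fstat = if (length(predictors) == 0) NA_real_
            else unname(sm$fstatistic[1]),
    coefficients = sm$coefficients[, 1:2, drop = FALSE]
  ), class = "ols_fit")
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Log-likelihood.
#' @param k Number of estimated parameters (including error variance).
#' @param n Sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' The candidate model set for local (node-level) analyses
#'
#' Fourteen specifications: the null model, each landscape variable alone,
#' home-range overlap alone, and each landscape variable together with
#' overlap. Landscape variables are never combined with one another because
#' they are mutually correlated (see [correlation_screen()]).
#'
#' @param landscape Names of the (six) landscape variables.
#' @param overlap Name of the home-range overlap variable.
#' @return A list of character vectors of predictor names (empty = null).
#' @export
local_candidate_set <- function(landscape, overlap = "hr_overlap") {
  specs <- c(
    list(character(0)),
    lapply(landscape, function(v) v),
    list(overlap),
    lapply(landscape, function(v) c(v, overlap))
  )
  names(specs) <- vapply(specs, function(p)
    if (length(p) == 0) "null" else paste(p, collapse = " + "), character(1))
  specs
}

#' Rank fitted models by AICc
#'
#' @param fits A list of `ols_fit` objects sharing the same data.
#' @param delta_top Threshold flagging the top set (default 2).
#' @return A data frame sorted by AICc with `model`, `k`, `aicc`, `delta`,
#'   `weight` (Akaike weights, summing to 1), `r2` and `top`.
#' @export
select_models <- function(fits, delta_top = 2) {
  if (length(fits) == 0) stop("no fitted models")
  a <- vapply(fits, function(f) aicc(f$loglik, f$k, f$n), numeric(1))
  delta <- a - min(a)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(
    model = vapply(fits, `[[`, character(1), "label"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    aicc = a, delta = delta, weight = w,
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$aicc), , drop = FALSE]
  out$delta <- out$aicc - out$aicc[1]
  out$top <- out$delta < delta_top
  rownames(out) <- NULL
  out
}

#' Model-averaged coefficients and relative variable importance
#'
#' For each variable: the Akaike-weight average of its coefficient over the
#' models containing it (weights renormalized within that subset — the
#' conditional average), an unconditional 95% CI combining within-model
#' variance and between-model spread, and the relative importance (the
#' unrenormalized sum of Akaike weights of models containing the variable).
#' `method = "full"` instead averages over the whole set substituting 0
#' where the variable is absent.
#'
#' @param fits List of `ols_fit` objects (the full candidate set).
#' @param variables Variables to average; default every predictor used.
#' @param method `"conditional"` (default) or `"full"`.
#' @return Data frame with `variable`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `importance`.
#' @export
model_average <- function(fits, variables = NULL,
                          method = c("conditional", "full")) {
  method <- match.arg(method)
  a <- vapply(fits, function(f) aicc(f$loglik, f$k, f$n), numeric(1))
  w <- exp(-(a - min(a)) / 2)
  w <- w / sum(w)
  if (is.null(variables))
    variables <- unique(unlist(lapply(fits, `[[`, "predictors")))
  if (length(variables) == 0) stop("no variables to average")
  rows <- lapply(variables, function(v) {
    has <- vapply(fits, function(f) v %in% f$predictors, logical(1))
    if (!any(has)) stop("variable '", v, "' appears in no model")
    beta <- vapply(fits[has], function(f) f$coefficients[v, 1], numeric(1))
    se <- vapply(fits[has], function(f) f$coefficients[v, 2], numeric(1))
    wv <- w[has]
    if (method == "conditional") {
      wv <- wv / sum(wv)
      est <- sum(wv * beta)
      use <- sqrt(sum(wv * (se^2 + (beta - est)^2)))
    } else {
      est <- sum(w[has] * beta)  # zeros elsewhere add nothing
      use <- sqrt(sum(w[has] * (se^2 + (beta - est)^2)) +
                  sum(w[!has]) * est^2)
    }
    data.frame(variable = v, estimate = est, se = use,
               ci_low = est - 1.96 * use, ci_high = est + 1.96 * use,
               importance = sum(w[has]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test of a regression F statistic
#'
#' The response is permuted uniformly at random `n_perm` times and the model
#' F statistic recomputed for each permutation; the observed model is
#' called significant when its F exceeds the 95th percentile of the
#' permuted values.
#'
#' @param y Response vector.
#' @param x Data frame/matrix of predictors.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @param level Exceedance level (default 0.95).
#' @return A list with `observed_F`, `permuted_F`, `exceedance_quantile`
#'   (the `level` percentile of the permuted values), `p_value`
#'   (`(1 + #{perm >= obs}) / (1 + n_perm)`) and `significant`.
#' @export
permutation_F <- function(y, x, n_perm = 9999, seed = 1L, level = 0.95) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  x <- as.matrix(as.data.frame(x))
  n <- length(y)
  p <- ncol(x)
  if (n <= p + 1) stop("too few observations")
  X <- cbind(1, x)
  Q <- qr.Q(qr(X))
  fstat <- function(Y) {
    # Y: n x m matrix of responses
    qty2 <- colSums((crossprod(Q, Y))^2)
    tss <- colSums(Y^2) - n * colMeans(Y)^2
    ess <- qty2 - n * colMeans(Y)^2
    rss <- pmax(tss - ess, 0)
    (ess / p) / (rss / (n - p - 1))
  }
  obs <- fstat(matrix(y, ncol = 1))
  set.seed(seed)
  perm <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- y[sample.int(n)]
  pf <- fstat(perm)
  q <- stats::quantile(pf, level, names = FALSE)
  list(observed_F = obs, permuted_F = pf, exceedance_quantile = q,
       p_value = (1 + sum(pf >= obs)) / (1 + n_perm),
       significant = obs > q)
}

#' Screen predictor pairs for collinearity
#'
#' Lists all pairs of predictors whose absolute Pearson correlation exceeds
#' the threshold; used to justify keeping at most one landscape variable
#' per candidate model.
#'
#' @param x Data frame/matrix of predictors (>= 2 columns).
#' @param r_threshold Absolute correlation threshold (default 0.5).
#' @return Data frame `var_a`, `var_b`, `r` of flagged pairs (zero rows if
#'   none).
#' @export
correlation_screen <- function(x, r_threshold = 0.5) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least two predictors")
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(!is.finite(sds) | sds == 0))
    stop("constant column: ", names(x)[which(!is.finite(sds) | sds == 0)[1]])
  cm <- stats::cor(x)
  idx <- which(upper.tri(cm) & abs(cm) > r_threshold, arr.ind = TRUE)
  data.frame(var_a = colnames(cm)[idx[, 1]], var_b = colnames(cm)[idx[, 2]],
             r = cm[idx], stringsAsFactors = FALSE)
}

#' Univariate cross-network regressions
#'
#' One simple linear regression of the network-level response (mean
#' subset-normalised closeness) on each landscape variable, variables
#' z-scored across networks; models are compared by variance explained
#' since they share a parameter count.
#'
#' @param closeness Numeric response, one value per network (n >= 3).
#' @param landscape Data frame of landscape variables, one row per network.
#' @return Data frame ranked by R^2 with `variable`, `coefficient`
#'   (standardized), `se`, `r2`, `p`.
#' @export
global_univariate <- function(closeness, landscape) {
  n <- length(closeness)
  if (n < 3) stop("need at least 3 networks")
  landscape <- as.data.frame(landscape)
  if (nrow(landscape) != n) stop("one row per network required")
  z <- standardize(landscape)
  rows <- lapply(names(z), function(v) {
    fit <- stats::lm(closeness ~ z[[v]])
    sm <- summary(fit)
    data.frame(variable = v,
               coefficient = unname(stats::coef(fit)[2]),
               se = sm$coefficients[2, 2],
               r2 = sm$r.squared,
               p = sm$coefficients[2, 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the 14-model local candidate set
#'
#' Convenience wrapper: Box-Cox transforms the response (lambda estimated
#' from the data unless supplied), z-scores the predictors, fits the
#' candidate set of [local_candidate_set()] and ranks it by AICc.
#'
#' @param data Data frame with the response and predictor columns.
#' @param response Response column name (positive values).
#' @param landscape Landscape variable names.
#' @param overlap Overlap variable name.
#' @param lambda Box-Cox lambda; `NULL` (default) estimates it by profile
#'   likelihood.
#' @return A list with `table` (from [select_models()]), `fits`, `lambda`,
#'   and `averaged` (from [model_average()]).
#' @export
fit_local_models <- function(data, response, landscape,
                             overlap = "hr_overlap", lambda = NULL) {
  y <- data[[response]]
  if (is.null(lambda))
    lambda <- boxcox_lambda(y, data[, c(landscape, overlap), drop = FALSE])
  d <- standardize(data[, c(landscape, overlap), drop = FALSE])
  d$.y <- boxcox_transform(y, lambda)
  specs <- local_candidate_set(landscape, overlap)
  fits <- lapply(names(specs), function(nm)
    fit_ols(d, ".y", specs[[nm]], label = nm))
  list(table = select_models(fits), fits = fits, lambda = lambda,
       averaged = model_average(fits))
}
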