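#' Fit a single-descriptor polynomial QSPR model
#'
#' Ordinary least squares of a property on the raw monomial design
#' `[1, x]` (linear) or `[1, x, x^2, x^3]` (cubic), the two model forms of
#' the study. Raw monomials (not orthogonal polynomials) are used so the
#' coefficients are directly comparable with published equations.
#'
#' @param x numeric regressor (a topological-index column).
#' @param y numeric response (a property column).
#' @param degree 1 (linear) or 3 (cubic).
#' @param regressor,response optional names carried into the fit.
#' @return object of class `qspr_fit`: list with `form` (`"linear"` or
#'   `"cubic"`), `degree`, `coefficients` (`beta0..beta<degree>`), `n`,
#'   `regressor`, `response` and `stats` (see [fit_statistics()]).
#' @examples
#' fit_polynomial(c(0, 1, 2), c(1, 3, 5), 1)$coefficients  # beta0=1, beta1=2
#' @export
fit_polynomial <- function(x, y, degree = 1, regressor = "TI", response = "y") {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (!degree %in% c(1, 3)) stop("degree must be 1 (linear) or 3 (cubic)")
  n <- length(x)
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y")
  if (n <= degree + 1) stop("need more than degree + 1 observations")
  if (length(unique(x)) < degree + 1)
    stop("rank-deficient design: x has too few distinct values")
  lmfit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  if (lmfit$rank < degree + 1 || anyNA(stats::coef(lmfit)))
    stop("rank-deficient design")
  # raw cubic designs on large-magnitude descriptors are ill-conditioned
  # (though full rank); record the condition number as a diagnostic
  sv <- svd(stats::model.matrix(lmfit), nu = 0, nv = 0)$d
  beta <- unname(stats::coef(lmfit))
  fit <- structure(list(
    form = if (degree == 1) "linear" else "cubic",
    degree = degree,
    coefficients = stats::setNames(beta, paste0("beta", 0:degree)),
    n = n,
    regressor = regressor,
    response = response,
    condition_number = max(sv) / min(sv)
  ), class = "qspr_fit")
  fit$stats <- fit_statistics(fit, x, y)
  fit
}

#' Statistics panel for a QSPR fit
#'
#' Computes the panel reported alongside each fitted equation:
#' `R_squared = 1 - RSS/TSS`, `R = +sqrt(R_squared)` (magnitude, as
#' published), residual standard error `S_E = sqrt(RSS/(n-k-1))`,
#' `F = (R^2/k) / ((1-R^2)/(n-k-1))` with `k` the polynomial degree, and the
#' upper-tail p-value of `F` under the F(k, n-k-1) distribution.
#'
#' @param fit a `qspr_fit`.
#' @param x,y the data the fit was produced from.
#' @return named list with `R`, `R_squared`, `S_E`, `F_stat`, `p_value`,
#'   `RSS`, `TSS`.
#' @export
fit_statistics <- function(fit, x, y) {
  stopifnot(inherits(fit, "qspr_fit"), length(x) == length(y))
  yhat <- predict(fit, x)
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("constant response: R_squared undefined")
  k <- fit$degree
  n <- length(y)
  r2 <- 1 - rss / tss
  fstat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  list(
    R = sqrt(max(r2, 0)),
    R_squared = r2,
    S_E = sqrt(rss / (n - k - 1)),
    F_stat = fstat,
    p_value = stats::pf(fstat, k, n - k - 1, lower.tail = FALSE),
    RSS = rss,
    TSS = tss
  )
}

#' Predict from a QSPR polynomial fit
#'
#' @param object a `qspr_fit`.
#' @param newdata numeric vector of regressor values.
#' @param ... unused.
#' @return numeric predictions (polynomial evaluation).
#' @export
predict.qspr_fit <- function(object, newdata, ...) {
  stopifnot(is.numeric(newdata))
  beta <- object$coefficients
  out <- rep(beta[[1L]], length(newdata))
  for (j in seq_len(object$degree)) out <- out + beta[[j + 1L]] * newdata^j
  out
}

#' @export
print.qspr_fit <- function(x, ...) {
  co <- signif(x$coefficients, 6)
  terms <- c(co[1L], sprintf("%s*x^%d", co[-1L], seq_len(x$degree)))
  cat(sprintf("%s fit: %s ~ %s\n  y = %s\n  R2 = %.4f, S_E = %.4f, F = %.3f, p = %.3g (n = %d)\n",
              x$form, x$response, x$regressor, paste(terms, collapse = " + "),
              x$stats$R_squared, x$stats$S_E, x$stats$F_stat, x$stats$p_value, x$n))
  invisible(x)
}

#' Per-index statistics table: all properties, linear and cubic forms
#'
#' Mirrors the study's per-index tables: for one descriptor, each of the
#' seven properties is fitted with the linear and the cubic model, giving 14
#' rows of coefficients and statistics.
#'
#' @param records drug table as returned by [load_drug_table()] (or any data
#'   frame with the descriptor and property columns).
#' @param index_name one of [index_names()].
#' @param properties property columns to fit (default all seven).
#' @return data frame with columns `index`, `property`, `form`,
#'   `beta0..beta3` (`NA` where absent), `R`, `R_squared`, `S_E`, `F_stat`,
#'   `p_value`.
#' @export
qspr_table <- function(records, index_name,
                       properties = intersect(.property_names, names(records))) {
  if (nrow(records) < 5L) stop("need at least 5 records")
  if (!index_name %in% names(records)) stop("unknown index name: ", index_name)
  if (!all(properties %in% names(records)))
    stop("unknown property name: ", paste(setdiff(properties, names(records)), collapse = ", "))
  x <- records[[index_name]]
  rows <- lapply(properties, function(prop) {
    do.call(rbind, lapply(c(1, 3), function(deg) {
      fit <- fit_polynomial(x, records[[prop]], deg,
                            regressor = index_name, response = prop)
      beta <- rep(NA_real_, 4L)
      beta[seq_len(deg + 1L)] <- fit$coefficients
      data.frame(index = index_name, property = prop, form = fit$form,
                 beta0 = beta[1L], beta1 = beta[2L], beta2 = beta[3L],
                 beta3 = beta[4L],
                 R = fit$stats$R, R_squared = fit$stats$R_squared,
                 S_E = fit$stats$S_E, F_stat = fit$stats$F_stat,
                 p_value = fit$stats$p_value,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-property prediction table: actual versus fitted values
#'
#' Mirrors the study's actual-versus-predicted tables: for one property,
#' each descriptor is used to fit linear and cubic models and the fitted
#' values for all drugs are tabulated next to the actual column.
#'
#' @param records drug table as returned by [load_drug_table()].
#' @param property_name one of the seven property columns.
#' @param indices descriptor columns to use (default all ten).
#' @return data frame whose first row is the actual values (`form =
#'   "actual"`) followed by one row per index and form; drug names are the
#'   value columns.
#' @export
prediction_table <- function(records, property_name, indices = index_names()) {
  if (!property_name %in% names(records))
    stop("unknown property name: ", property_name)
  if (!all(indices %in% names(records)))
    stop("unknown index name: ", paste(setdiff(indices, names(records)), collapse = ", "))
  y <- records[[property_name]]
  rows <- list(data.frame(index = "", form = "actual",
                          t(stats::setNames(y, records$name)),
                          check.names = FALSE, stringsAsFactors = FALSE))
  for (idx in indices) {
    for (deg in c(1, 3)) {
      fit <- fit_polynomial(records[[idx]], y, deg,
                            regressor = idx, response = property_name)
      pred <- predict(fit, records[[idx]])
      rows[[length(rows) + 1L]] <- data.frame(
        index = idx, form = fit$form,
        t(stats::setNames(pred, records$name)),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
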