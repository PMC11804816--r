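## QSPR regression: linear and quadratic property ~ index models.

#' Overall-model F statistic from the coefficient of determination
#'
#' F = (r2 / k) / ((1 - r2) / (n - k - 1)), the usual test of a k-predictor
#' OLS model against the intercept-only model.
#'
#' @param r2 coefficient of determination, in [0, 1).
#' @param n sample size (> k + 1).
#' @param k number of predictors (1 for linear, 2 for quadratic).
#' @return non-negative numeric scalar.
#' @examples
#' fStatistic(0.4359, 13, 1)  # ~ 8.50
#' @export
fStatistic <- function(r2, n, k) {
  stopifnot(n > k + 1, k >= 1, r2 >= 0)
  if (r2 >= 1) stop("r2 = 1: F statistic is infinite")
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Upper-tail p-value of an F statistic
#'
#' @param f observed F statistic, >= 0.
#' @param df1 numerator degrees of freedom (number of predictors).
#' @param df2 denominator degrees of freedom (n - df1 - 1).
#' @return probability that an F(df1, df2) variate exceeds `f`.
#' @examples
#' pFromF(8.498, 1, 11)  # ~ 0.0141
#' @export
pFromF <- function(f, df1, df2) {
  stopifnot(f >= 0, df1 >= 1, df2 >= 1)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Fit a linear or quadratic QSPR model
#'
#' Ordinary least squares of a property `y` on an index `x` (linear,
#' Y = alpha + beta X) or on `x` and `x^2` (quadratic,
#' Y = alpha + beta X + gamma X^2). The reported correlation `r` is the
#' multiple correlation sqrt(r2) and is therefore non-negative even when the
#' slope is negative (matching the convention of published QSPR tables); the
#' signed slope is available as `beta`. A numerically perfect fit reports
#' r2 = 1 with an infinite F and zero p.
#'
#' @param x numeric index values.
#' @param y numeric property values, same length as `x`.
#' @param kind `"linear"` or `"quadratic"`.
#' @return a \linkS4class{RegressionFit}.
#' @examples
#' props <- drugProperties(); idx <- paperIndices()
#' fitPropertyModel(idx$ga4, props$C, "linear")  # r = 0.6602, F = 8.498
#' @export
fitPropertyModel <- function(x, y, kind = c("linear", "quadratic")) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y")
  k <- if (kind == "linear") 1L else 2L
  if (length(x) < k + 2L) {
    stop("need at least ", k + 2L, " observations for a ", kind, " fit")
  }
  ndistinct <- length(unique(x))
  if (ndistinct < k + 1L) {
    stop("constant or rank-deficient predictor: only ", ndistinct,
         " distinct x value(s)")
  }
  fit <- if (kind == "linear") {
    stats::lm(y ~ x)
  } else {
    stats::lm(y ~ x + I(x^2))
  }
  cf <- stats::coef(fit)
  sst <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  if (sst == 0) stop("constant response: r2 undefined")
  r2 <- 1 - sse / sst
  r2 <- min(max(r2, 0), 1)
  n <- length(x)
  perfect <- (1 - r2) < 1e-12
  f <- if (perfect) Inf else fStatistic(r2, n, k)
  p <- if (perfect) 0 else pFromF(f, k, n - k - 1L)
  new("RegressionFit",
      kind = kind,
      alpha = unname(cf[1L]),
      beta = unname(cf[2L]),
      gamma = if (kind == "quadratic") unname(cf[3L]) else NA_real_,
      r = sqrt(r2), r2 = r2, f = f, p = p, n = n)
}

#' Significance screen of a QSPR fit
#'
#' Applies the three published screening rules: p-value at most 0.05,
#' F statistic strictly greater than 2.5, and correlation strictly greater
#' than 0.7.
#'
#' @param fit a \linkS4class{RegressionFit}.
#' @return named logical vector `c(p_ok, f_ok, r_ok, overall)` where
#'   `overall` is the conjunction of the three screens.
#' @export
significance <- function(fit) {
  stopifnot(is(fit, "RegressionFit"))
  flags <- c(p_ok = fit@p <= 0.05,
             f_ok = fit@f > 2.5,
             r_ok = fit@r > 0.7)
  c(flags, overall = all(flags))
}

#' Fit every property ~ index combination
#'
#' Crosses the eight index columns with the eight property columns and fits
#' the requested model kinds, collecting coefficients, statistics and
#' significance flags in one long table. Constant predictor columns are
#' reported as rows with NA statistics rather than aborting the run.
#'
#' @param indices data.frame with a `drug` id column and the index columns
#'   `zeta`, `avec`, `m1_star`, `m1_dstar`, `m2_star`, `ga4`, `abc`, `he`
#'   (the layout of [paperIndices()] and [indicesTable()]).
#' @param props data.frame with a `drug` id column and property columns
#'   `BP`, `MP`, `E`, `FP`, `MR`, `C`, `MW`, `R` (the layout of
#'   [drugProperties()]).
#' @param models subset of `c("linear", "quadratic")`.
#' @return data.frame with one row per (property, index, model) and columns
#'   `property`, `index`, `model`, `alpha`, `beta`, `gamma`, `r`, `r2`, `f`,
#'   `p`, `n`, `p_ok`, `f_ok`, `r_ok`, `significant`.
#' @export
fitAllModels <- function(indices, props,
                         models = c("linear", "quadratic")) {
  models <- match.arg(models, several.ok = TRUE)
  if (!"drug" %in% names(indices) || !"drug" %in% names(props)) {
    stop("both tables need a 'drug' id column")
  }
  if (!setequal(indices$drug, props$drug)) {
    stop("drug ids of the two tables do not match")
  }
  props <- props[match(indices$drug, props$drug), , drop = FALSE]
  propCols <- c("BP", "MP", "E", "FP", "MR", "C", "MW", "R")
  missingProp <- setdiff(propCols, names(props))
  if (length(missingProp)) {
    stop("missing property column(s): ", paste(missingProp, collapse = ", "))
  }
  missingIdx <- setdiff(.indexColumns, names(indices))
  if (length(missingIdx)) {
    stop("missing index column(s): ", paste(missingIdx, collapse = ", "))
  }
  rows <- list()
  for (model in models) {
    for (ix in .indexColumns) {
      for (pr in propCols) {
        fit <- tryCatch(
          fitPropertyModel(indices[[ix]], props[[pr]], model),
          error = function(e) NULL
        )
        rows[[length(rows) + 1L]] <- if (is.null(fit)) {
          data.frame(property = pr, index = ix, model = model,
                     alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                     r = NA_real_, r2 = NA_real_, f = NA_real_, p = NA_real_,
                     n = length(indices[[ix]]),
                     p_ok = NA, f_ok = NA, r_ok = NA, significant = NA,
                     stringsAsFactors = FALSE)
        } else {
          fl <- significance(fit)
          data.frame(property = pr, index = ix, model = model,
                     alpha = fit@alpha, beta = fit@beta, gamma = fit@gamma,
                     r = fit@r, r2 = fit@r2, f = fit@f, p = fit@p, n = fit@n,
                     p_ok = unname(fl["p_ok"]), f_ok = unname(fl["f_ok"]),
                     r_ok = unname(fl["r_ok"]),
                     significant = unname(fl["overall"]),
                     stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Index-by-property correlation table
#'
#' The 8 x 8 matrix of multiple correlation coefficients r for one model
#' kind, mirroring the published comparison tables (indices as rows,
#' properties as columns).
#'
#' @inheritParams fitAllModels
#' @param model `"linear"` or `"quadratic"`.
#' @param digits rounding applied for display; use `NULL` for full
#'   precision.
#' @return numeric matrix with index rownames and property colnames.
#' @export
correlationTable <- function(indices, props,
                             model = c("linear", "quadratic"),
                             digits = 4) {
  model <- match.arg(model)
  fits <- fitAllModels(indices, props, models = model)
  propCols <- c("BP", "MP", "E", "FP", "MR", "C", "MW", "R")
  out <- matrix(NA_real_, nrow = length(.indexColumns),
                ncol = length(propCols),
                dimnames = list(.indexColumns, propCols))
  for (i in seq_len(nrow(fits))) {
    out[fits$index[i], fits$property[i]] <- fits$r[i]
  }
  if (!is.null(digits)) out <- round(out, digits)
  out
}
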