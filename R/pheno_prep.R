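#' Exclude extreme trait values
#'
#' Marks values differing from the trait mean by more than `k` standard
#' deviations as missing. Mean and SD are computed once over the non-missing
#' values (single pass, no re-iteration after exclusion).
#'
#' @param y Numeric trait vector (missing values allowed).
#' @param k SD multiple beyond which a value is an outlier; default 5.
#' @return `y` with outliers set to `NA`; the indices of excluded values are
#'   attached as attribute `"excluded"`.
#' @export
remove_outliers <- function(y, k = 5) {
  ok <- is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 non-missing values")
  mu <- mean(y[ok])
  sdv <- stats::sd(y[ok])
  out <- which(ok & abs(y - mu) > k * sdv)
  y[out] <- NA_real_
  attr(y, "excluded") <- out
  y
}

#' Covariate adjustment and z-score normalization
#'
#' Implements the common phenotype workflow: fit an ordinary least squares
#' model of the trait on age (numeric) and sex / generation wave / diet
#' (indicator-coded factors), then z-score the residuals. Covariates with a
#' single observed level are dropped from the design; diet may instead be
#' declared numeric (days on diet) via `diet_numeric`. Individuals with
#' missing trait or covariate values stay missing in the output.
#'
#' @param y Named numeric trait vector (names are individual IDs).
#' @param covars Data frame of covariates with rownames (or an `id` column)
#'   matching `names(y)`; recognised columns: `age`, `sex`, `generation`,
#'   `diet`. Any subset may be present. `NULL` skips adjustment and only
#'   z-scores.
#' @param diet_numeric Treat `diet` as a continuous days-on-diet term
#'   instead of a factor.
#' @return Named numeric vector of z-scored residuals (mean 0, SD 1 over the
#'   non-missing entries; sample SD with the n-1 denominator).
#' @export
adjust_and_normalize <- function(y, covars = NULL, diet_numeric = FALSE) {
  if (is.null(names(y))) names(y) <- as.character(seq_along(y))
  if (is.null(covars)) return(zscore(y))
  if (!is.null(covars$id)) {
    rownames(covars) <- covars$id
    covars$id <- NULL
  }
  cv <- covars[names(y), , drop = FALSE]
  keep <- intersect(c("age", "sex", "generation", "diet"), names(cv))
  cv <- cv[, keep, drop = FALSE]
  for (col in keep) {
    if (col == "age" || (col == "diet" && diet_numeric))
      cv[[col]] <- as.numeric(cv[[col]])
    else cv[[col]] <- factor(cv[[col]])
  }
  use <- is.finite(y) & stats::complete.cases(cv)
  # single-level factors carry no information and break model.matrix
  dropped <- vapply(keep, function(col)
    is.factor(cv[[col]]) && length(unique(cv[use, col])) < 2, logical(1))
  form_terms <- keep[!dropped]
  out <- rep(NA_real_, length(y))
  names(out) <- names(y)
  if (length(form_terms) == 0) {
    out[use] <- as.vector(scale(y[use]))
    return(out)
  }
  dat <- droplevels(cbind(.y = y, cv)[use, c(".y", form_terms), drop = FALSE])
  X <- stats::model.matrix(
    stats::reformulate(form_terms, response = NULL), data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qrX, dat$.y)
  out[use] <- as.vector(scale(res))
  out
}

#' z-score a vector over its non-missing entries
#'
#' @param y Numeric vector.
#' @return Vector with non-missing entries standardized to mean 0, sample
#'   SD 1; missing entries preserved.
#' @export
zscore <- function(y) {
  ok <- is.finite(y)
  y[ok] <- (y[ok] - mean(y[ok])) / stats::sd(y[ok])
  y[!ok] <- NA_real_
  y
}
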