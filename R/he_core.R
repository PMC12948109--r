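#' Haseman-Elston regression of pairwise trait products on kinship
#'
#' Regresses phenotypic similarity — the product of z-normalized trait
#' values over pairs of distinct individuals — on pairwise kinship. For a
#' single trait (or two traits measured on the same animals) every unordered
#' pair \{i, j\} contributes one observation; for two traits on the same
#' animals the response is symmetrized, `(M_i N_j + M_j N_i) / 2`. When the
#' two cohorts overlap only partially, animals present in one cohort
#' contribute single cross-cohort products and overlapping pairs are
#' symmetrized, so no pair is double-counted in the standard error.
#'
#' The slope's standard error uses Fisher's regression-coefficient formula
#' `SE(beta) = S_eps / sqrt(sum((x - xbar)^2))` with the residual standard
#' error `S_eps = sqrt(RSS / (n_pairs - 2))`, and the p-value is a two-sided
#' t test with `n_pairs - 2` degrees of freedom. Pair products are not
#' independent observations, so these p-values are anti-conservative; that
#' miscalibration is exactly what the empirical correction factor
#' [correction_factor()] repairs in the standard errors.
#'
#' @param M Named numeric vector of z-normalized trait values (names are
#'   individual IDs present in `K`). Missing values are allowed; pairs
#'   containing a missing value are dropped.
#' @param N Second trait vector for cross-trait regression, or `NULL` for
#'   the single-trait (heritability) regression.
#' @param K Kinship matrix covering every individual appearing in `M`/`N`.
#' @return List with `beta`, `intercept`, `se` (raw, Fisher), `p`,
#'   `n_pairs`, `n_animals`.
#' @seealso [he_h2()], [he_rg()]
#' @export
he_fit <- function(M, N = NULL, K) {
  if (is.null(names(M))) stop("'M' must be named by individual ID")
  a <- M[is.finite(M)]
  if (is.null(N)) {
    b <- a
  } else {
    if (is.null(names(N))) stop("'N' must be named by individual ID")
    b <- N[is.finite(N)]
  }
  if (!all(names(a) %in% rownames(K)) || !all(names(b) %in% rownames(K)))
    stop("kinship matrix does not cover all phenotyped individuals")
  same_set <- setequal(names(a), names(b))
  if (same_set) {
    v <- a
    w <- b[names(a)]
    fit <- .he_suffstats(v, w, K[names(a), names(a)])
  } else {
    fit <- .he_pairs(a, b, K)
  }
  if (fit$n_pairs < 3) stop("fewer than 3 usable pairs")
  if (fit$sxx_c <= 0) stop("zero kinship variance across pairs")
  beta <- fit$sxy_c / fit$sxx_c
  alpha <- (fit$sy - beta * fit$sx) / fit$n_pairs
  rss <- fit$syy + fit$n_pairs * alpha^2 + beta^2 * fit$sxx +
    2 * alpha * beta * fit$sx - 2 * alpha * fit$sy - 2 * beta * fit$sxy
  rss <- max(rss, 0)
  se <- sqrt(rss / (fit$n_pairs - 2)) / sqrt(fit$sxx_c)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = fit$n_pairs - 2)
  list(beta = beta, intercept = alpha, se = se, p = p,
       n_pairs = fit$n_pairs, n_animals = fit$n_animals)
}

# Closed-form pair sums for two traits on an identical animal set.
# For unordered pairs i<j with response y_ij = (v_i w_j + v_j w_i)/2 and
# regressor x_ij = K_ij, all five sums reduce to O(n^2) matrix expressions;
# no pair enumeration is materialized.
.he_suffstats <- function(v, w, K) {
  n <- length(v)
  np <- n * (n - 1) / 2
  dK <- diag(K)
  sx <- (sum(K) - sum(dK)) / 2
  sxx <- (sum(K * K) - sum(dK^2)) / 2
  sv <- sum(v); sw <- sum(w)
  svw <- sum(v * w)
  sy <- (sv * sw - svw) / 2
  syy <- (sum(v^2) * sum(w^2) + svw^2 - 2 * sum((v * w)^2)) / 4
  sxy <- (drop(crossprod(v, K %*% w)) - sum(dK * v * w)) / 2
  list(sx = sx, sxx = sxx, sy = sy, syy = syy, sxy = sxy,
       sxx_c = sxx - sx^2 / np, sxy_c = sxy - sx * sy / np,
       n_pairs = np, n_animals = n)
}

# General path: cohorts differ (disjoint or partially overlapping).  All
# ordered cross products a_i b_j (i != j) are formed, then collapsed onto
# unordered pairs; a pair observed in both orientations contributes its
# symmetrized mean once.
.he_pairs <- function(a, b, K) {
  ia <- match(names(a), rownames(K))
  ib <- match(names(b), rownames(K))
  na <- length(a); nb <- length(b)
  resp <- as.vector(outer(unname(a), unname(b)))
  kin <- as.vector(K[ia, ib, drop = FALSE])
  I <- rep(ia, times = nb)
  J <- rep(ib, each = na)
  keep <- I != J
  lo <- pmin(I[keep], J[keep])
  hi <- pmax(I[keep], J[keep])
  key <- (lo - 1) * nrow(K) + hi
  cnt <- rowsum(rep(1, length(key)), key)
  y <- rowsum(resp[keep], key) / cnt
  x <- rowsum(kin[keep], key) / cnt
  np <- length(y)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  list(sx = sx, sxx = sxx, sy = sy, syy = syy, sxy = sxy,
       sxx_c = sxx - sx^2 / np, sxy_c = sxy - sx * sy / np,
       n_pairs = np, n_animals = length(union(names(a), names(b))))
}

#' Heritability via Haseman-Elston regression
#'
#' For a z-normalized trait the HE slope equals twice the narrow-sense
#' heritability, so `h2 = beta / 2` and `SE(h2) = SE(beta) / 2`. The
#' corrected standard error multiplies the raw (Fisher) standard error by
#' the empirical correction factor `F(h2, n)` evaluated at the point
#' estimate (clipped to \[0, 1\]) and the number of animals.
#'
#' @param M Named, z-normalized trait vector.
#' @param K Kinship matrix.
#' @param coefficients Optional [correction_coefficients()] overriding the
#'   package's empirically derived defaults.
#' @return Object of class `"he_estimate"`: list with `beta`, `h2`,
#'   `se_raw`, `se_corrected`, `p`, `n_animals`, `n_pairs`.
#' @examples
#' G <- simulate_genotypes(300, 300, seed = 5)
#' tr <- simulate_trait(G, h2 = 0.4, seed = 6)
#' est <- he_h2(zscore(tr$values), kinship_from_genotypes(G))
#' est$h2
#' @export
he_h2 <- function(M, K, coefficients = NULL) {
  fit <- he_fit(M, NULL, K)
  h2 <- fit$beta / 2
  se_raw <- fit$se / 2
  F <- correction_factor(h2, fit$n_animals, coefficients)
  structure(list(beta = fit$beta, h2 = h2, se_raw = se_raw,
                 se_corrected = se_raw * F, p = fit$p,
                 n_animals = fit$n_animals, n_pairs = fit$n_pairs),
            class = "he_estimate")
}

#' @export
print.he_estimate <- function(x, ...) {
  cat(sprintf("HE h2 = %.4f (SE %.4f raw, %.4f corrected), p = %.3g, n = %d (%d pairs)\n",
              x$h2, x$se_raw, x$se_corrected, x$p, x$n_animals, x$n_pairs))
  invisible(x)
}

#' Genetic correlation via cross-trait Haseman-Elston regression
#'
#' The cross-trait HE slope divided by two is the genetic covariance
#' `rho = beta_MN / 2`; the genetic correlation is
#' `rg = rho / sqrt(h2_M * h2_N)`, estimable only when both heritabilities
#' are positive. The standard error propagates the relative variances of
#' the three ingredients:
#' `SE(rg) = |rg| * sqrt((SE(rho)/rho)^2 + (SE(h2_M)/(2 h2_M))^2 +
#' (SE(h2_N)/(2 h2_N))^2)`, computed in an algebraically equivalent form
#' that stays finite at `rho = 0`; the raw relative-variance sum is exposed
#' as `rel_var_sum` for audit. The correction factor applied to `SE(rho)`
#' is evaluated at the mean of the two heritabilities and the smaller of
#' the two cohort sizes.
#'
#' @param M,N Named, z-normalized trait vectors (possibly from different
#'   cohorts; kinship must cover all animals).
#' @param K Kinship matrix.
#' @param est_M,est_N Optional precomputed [he_h2()] estimates; computed
#'   from `M`/`N` when omitted.
#' @param corrected Use corrected standard errors in the propagation
#'   (default) or raw Fisher ones.
#' @param coefficients Optional correction-coefficient override.
#' @return Object of class `"rg_estimate"`: `rho`, `rg`, `se`, `p`,
#'   `h2_M`, `h2_N`, `n_M`, `n_N`, `n_pairs`, `valid` (per [filter_rg()]),
#'   `estimable`, `rel_var_sum`. Non-positive input heritability yields an
#'   explicit not-estimable result rather than `NaN`.
#' @export
he_rg <- function(M, N, K, est_M = NULL, est_N = NULL, corrected = TRUE,
                  coefficients = NULL) {
  if (is.null(est_M)) est_M <- he_h2(M, K, coefficients)
  if (is.null(est_N)) est_N <- he_h2(N, K, coefficients)
  base <- list(h2_M = est_M$h2, h2_N = est_N$h2,
               n_M = est_M$n_animals, n_N = est_N$n_animals)
  if (est_M$h2 <= 0 || est_N$h2 <= 0) {
    return(structure(c(list(rho = NA_real_, rg = NA_real_, se = NA_real_,
                            p = NA_real_, n_pairs = NA_integer_,
                            valid = FALSE, estimable = FALSE,
                            rel_var_sum = NA_real_), base),
                     class = "rg_estimate"))
  }
  fit <- he_fit(M, N, K)
  rho <- fit$beta / 2
  se_rho <- fit$se / 2
  if (corrected) {
    Fc <- correction_factor((est_M$h2 + est_N$h2) / 2,
                            min(est_M$n_animals, est_N$n_animals),
                            coefficients)
    se_rho <- se_rho * Fc
  }
  se_hM <- if (corrected) est_M$se_corrected else est_M$se_raw
  se_hN <- if (corrected) est_N$se_corrected else est_N$se_raw
  gm <- sqrt(est_M$h2 * est_N$h2)
  rg <- rho / gm
  term_M <- (se_hM / (2 * est_M$h2))^2
  term_N <- (se_hN / (2 * est_N$h2))^2
  se_rg <- sqrt((se_rho / gm)^2 + rg^2 * (term_M + term_N))
  rel_var_sum <- (se_rho / rho)^2 + term_M + term_N
  structure(c(list(rho = rho, rg = rg, se = se_rg, p = fit$p,
                   n_pairs = fit$n_pairs,
                   valid = filter_rg(rg, se_rg), estimable = TRUE,
                   rel_var_sum = rel_var_sum), base),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  if (!x$estimable)
    cat("rg not estimable (non-positive h2 input)\n")
  else
    cat(sprintf("rg = %.4f (SE %.4f), p = %.3g [h2: %.3f / %.3f]%s\n",
                x$rg, x$se, x$p, x$h2_M, x$h2_N,
                if (x$valid) "" else "  [outside validity band]"))
  invisible(x)
}

#' Empirical standard-error correction factor
#'
#' Raw Fisher standard errors of HE regression lose calibration as the
#' trait heritability and the cohort size grow, because pairwise products
#' become increasingly non-independent. The multiplicative correction
#' `F = sqrt(n) (0.020225 h2 + 0.004225) + (-0.2352 h2 + 0.9467)` restores
#' split-half calibration (`sigma_delta_norm ~ 1`, see
#' [calibration_experiment()]). `h2` is clipped to \[0, 1\] before
#' evaluation, making the function total.
#'
#' @param h2 Heritability point estimate.
#' @param n Number of animals in the cohort.
#' @param coefficients Optional [correction_coefficients()] object; the
#'   default carries the empirically derived values above.
#' @return The multiplier `F`; `SE_corrected = SE * F`.
#' @examples
#' correction_factor(0.4, 900)  # 1.22207
#' @export
correction_factor <- function(h2, n, coefficients = NULL) {
  if (is.null(coefficients)) coefficients <- correction_coefficients()
  h2 <- min(max(h2, 0), 1)
  sqrt(n) * (coefficients$slope_h2 * h2 + coefficients$slope_const) +
    (coefficients$int_h2 * h2 + coefficients$int_const)
}

#' Correction-factor coefficients
#'
#' Container for the four coefficients of the SE correction factor
#' `F = sqrt(n) (slope_h2 * h2 + slope_const) + (int_h2 * h2 + int_const)`.
#' Defaults are the package's empirically derived values; alternative sets
#' (e.g. re-derived via [derive_correction_coefficients()]) can be passed
#' to the estimation functions.
#'
#' @param slope_h2,slope_const Coefficients of the sqrt(n) term.
#' @param int_h2,int_const Coefficients of the constant term.
#' @return Object of class `"correction_coefficients"`.
#' @export
correction_coefficients <- function(slope_h2 = 0.020225,
                                    slope_const = 0.004225,
                                    int_h2 = -0.2352,
                                    int_const = 0.9467) {
  structure(list(slope_h2 = slope_h2, slope_const = slope_const,
                 int_h2 = int_h2, int_const = int_const),
            class = "correction_coefficients")
}

#' Standardized split-half difference of heritability estimates
#'
#' `Delta_norm = (h2_1 - h2_2) / sqrt(sigma2_1 + sigma2_2)`: the difference
#' of two independent heritability estimates in units of its expected
#' standard deviation. Over many replicate splits, the SD of these values
#' (`sigma_delta_norm`) should be approximately 1 when the standard errors
#' are correctly calibrated.
#'
#' @param est1,est2 `"he_estimate"` objects from [he_h2()].
#' @param corrected Use the corrected (default) or raw standard errors.
#' @return Signed standardized difference.
#' @export
delta_norm <- function(est1, est2, corrected = TRUE) {
  s1 <- if (corrected) est1$se_corrected else est1$se_raw
  s2 <- if (corrected) est2$se_corrected else est2$se_raw
  tot <- s1^2 + s2^2
  if (!is.finite(tot) || tot <= 0) stop("zero total variance in delta_norm")
  (est1$h2 - est2$h2) / sqrt(tot)
}

#' Split-half SE calibration experiment
#'
#' For every grid cell (h2, n): repeatedly simulate a population of `2 n`
#' individuals with an additive trait at heritability `h2`, split it into
#' two disjoint halves, estimate the heritability of each half by HE
#' regression, and record the standardized difference [delta_norm()]. The
#' SD of those values over replicates, `sigma_delta_norm`, measures SE
#' calibration: ~1 means correctly calibrated, >1 under-dispersed SEs.
#'
#' @param h2_grid Heritability values to simulate.
#' @param n_grid Per-half cohort sizes.
#' @param n_replicates Replicates per cell (a warning is issued below 30,
#'   where the SD estimate is unstable).
#' @param seed Integer seed for the whole experiment.
#' @param corrected Use corrected (default) or raw standard errors in the
#'   denominator of `Delta_norm`.
#' @param n_markers,n_causal,maf_pool Simulation-design parameters
#'   (defaults: 1,000 unlinked markers, 10 causal, MAFs sampled from
#'   \{0.05, 0.1, 0.3, 0.4\}).
#' @return Data frame with columns `h2`, `n`, `sigma_delta_norm`,
#'   `mean_delta_norm`, `n_replicates`.
#' @export
calibration_experiment <- function(h2_grid, n_grid, n_replicates, seed = NULL,
                                   corrected = TRUE, n_markers = 1000,
                                   n_causal = 10,
                                   maf_pool = c(0.05, 0.1, 0.3, 0.4)) {
  if (length(h2_grid) == 0 || length(n_grid) == 0)
    stop("empty grid")
  if (n_replicates < 30)
    warning("fewer than 30 replicates; sigma_delta_norm will be unstable")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(h2 = h2_grid, n = n_grid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    h2 <- grid$h2[g]; n <- grid$n[g]
    dn <- vapply(seq_len(n_replicates), function(r) {
      G <- simulate_genotypes(2 * n, n_markers, maf_pool)
      tr <- simulate_trait(G, h2, n_causal)
      halves <- split_half(rownames(G$dosages))
      ests <- lapply(halves, function(ids) {
        K <- kinship_from_genotypes(G$dosages[ids, , drop = FALSE])
        he_h2(zscore(tr$values[ids]), K)
      })
      delta_norm(ests[[1]], ests[[2]], corrected = corrected)
    }, numeric(1))
    data.frame(h2 = h2, n = n, sigma_delta_norm = stats::sd(dn),
               mean_delta_norm = mean(dn), n_replicates = n_replicates)
  })
  do.call(rbind, res)
}

#' Re-derive correction coefficients from a calibration table
#'
#' Two-stage least squares on a `sigma_delta_norm` table: first, for each
#' heritability level, regress `sigma_delta_norm` on `sqrt(n)`; second,
#' regress the stage-1 intercepts and slopes on `h2`. The four stage-2
#' coefficients define the correction factor (see [correction_factor()]).
#'
#' @param sigma_table Data frame with columns `h2`, `n`,
#'   `sigma_delta_norm` (as produced by [calibration_experiment()] with
#'   `corrected = FALSE`).
#' @return A [correction_coefficients()] object.
#' @export
derive_correction_coefficients <- function(sigma_table) {
  stopifnot(all(c("h2", "n", "sigma_delta_norm") %in% names(sigma_table)))
  h2s <- sort(unique(sigma_table$h2))
  if (length(h2s) < 2) stop("need at least two h2 levels")
  stage1 <- t(vapply(h2s, function(h) {
    sub <- sigma_table[sigma_table$h2 == h, ]
    if (length(unique(sub$n)) < 2) stop("need at least two n values per h2")
    stats::coef(stats::lm(sigma_delta_norm ~ sqrt(n), data = sub))
  }, numeric(2)))
  ints <- stats::coef(stats::lm(stage1[, 1] ~ h2s))
  slos <- stats::coef(stats::lm(stage1[, 2] ~ h2s))
  correction_coefficients(slope_h2 = unname(slos[2]),
                          slope_const = unname(slos[1]),
                          int_h2 = unname(ints[2]),
                          int_const = unname(ints[1]))
}

#' Heritability-based trait filter
#'
#' Keeps traits with `h2 >= h2_min` whose estimate does not exceed 1 by
#' more than its standard error (`h2 <= 1 + se`); both failure reasons are
#' recorded.
#'
#' @param estimates List of `"he_estimate"` objects (optionally named by
#'   trait), or a data frame with columns `h2` and `se`.
#' @param h2_min Minimum heritability, default 0.10.
#' @param corrected Use the corrected SE (default) in the upper-bound rule.
#' @return Data frame with `trait`, `h2`, `se`, `keep`, `reason`.
#' @export
filter_traits <- function(estimates, h2_min = 0.10, corrected = TRUE) {
  if (is.data.frame(estimates)) {
    h2 <- estimates$h2; se <- estimates$se
    trait <- if (!is.null(estimates$trait)) estimates$trait
             else as.character(seq_len(nrow(estimates)))
  } else {
    h2 <- vapply(estimates, `[[`, numeric(1), "h2")
    se <- vapply(estimates, function(e)
      if (corrected) e$se_corrected else e$se_raw, numeric(1))
    trait <- if (!is.null(names(estimates))) names(estimates)
             else as.character(seq_along(estimates))
  }
  low <- h2 < h2_min
  high <- h2 > 1 + se
  reason <- rep("", length(h2))
  reason[low] <- sprintf("h2 < %g", h2_min)
  reason[high] <- paste0(ifelse(low[high], paste0(reason[high], "; "), ""),
                         "h2 > 1 + SE")
  data.frame(trait = trait, h2 = h2, se = se, keep = !(low | high),
             reason = reason, stringsAsFactors = FALSE)
}

#' Validity band for a genetic-correlation estimate
#'
#' A genetic correlation is retained when it does not exceed 1 (or fall
#' below -1) by more than its standard error: valid iff
#' `-1 - se <= rg <= 1 + se`.
#'
#' @param rg Genetic-correlation estimate, or an `"rg_estimate"` object.
#' @param se Its standard error (ignored when `rg` is an object).
#' @return Logical validity flag.
#' @export
filter_rg <- function(rg, se = NULL) {
  if (inherits(rg, "rg_estimate")) {
    se <- rg$se
    rg <- rg$rg
  }
  if (!is.finite(rg) || !is.finite(se)) return(FALSE)
  rg >= -1 - se && rg <= 1 + se
}
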