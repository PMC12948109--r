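test_that("HE regression equals brute-force pair enumeration", {
  # parameterized over cohort layouts: same cohort, disjoint, overlapping
  for (seed in c(101, 102, 103)) {
    K <- toy_kinship(9, seed)
    set.seed(seed + 1)
    M <- named_rnorm(9)
    N <- named_rnorm(9)

    fit <- he_fit(M, NULL, K)
    b <- brute_he(M, M, K)
    expect_equal(fit$beta, b$beta, tolerance = 1e-10)
    expect_equal(fit$se, b$se, tolerance = 1e-10)
    expect_equal(fit$p, b$p, tolerance = 1e-10)
    expect_equal(fit$n_pairs, b$n_pairs)

    fit2 <- he_fit(M, N, K)          # cross-trait, same animals
    b2 <- brute_he(M, N, K)
    expect_equal(fit2$beta, b2$beta, tolerance = 1e-10)
    expect_equal(fit2$se, b2$se, tolerance = 1e-10)

    Md <- M[1:4]; Nd <- N[5:9]       # disjoint cohorts
    fit3 <- he_fit(Md, Nd, K)
    b3 <- brute_he(Md, Nd, K)
    expect_equal(fit3$beta, b3$beta, tolerance = 1e-10)
    expect_equal(fit3$se, b3$se, tolerance = 1e-10)
    expect_equal(fit3$n_pairs, b3$n_pairs)

    Mo <- M[1:6]; No <- N[4:9]       # partial overlap
    fit4 <- he_fit(Mo, No, K)
    b4 <- brute_he(Mo, No, K)
    expect_equal(fit4$beta, b4$beta, tolerance = 1e-10)
    expect_equal(fit4$se, b4$se, tolerance = 1e-10)
    expect_equal(fit4$n_pairs, b4$n_pairs)
  }
})

test_that("pair bookkeeping and degenerate inputs", {
  K <- toy_kinship(3, 104)
  set.seed(105)
  M <- named_rnorm(3)
  expect_equal(he_fit(M, NULL, K)$n_pairs, 3)  # C(3,2)
  # fewer than 3 usable pairs
  expect_error(he_fit(M[1:2], NULL, K), "pairs")
  # zero kinship variance
  Kflat <- matrix(0.25, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Kflat) <- 0.5
  expect_error(he_fit(named_rnorm(4, letters[1:4]), NULL, Kflat),
               "kinship variance")
  # missing values are dropped pairwise
  M2 <- named_rnorm(9, sprintf("i%02d", 1:9))
  K9 <- toy_kinship(9, 106)
  M2[c(2, 5)] <- NA
  expect_equal(he_fit(M2, NULL, K9)$n_animals, 7)
  expect_equal(he_fit(M2, NULL, K9)$n_pairs, choose(7, 2))
})

test_that("a trait unrelated to kinship structure gives a null slope", {
  set.seed(107)
  ok <- replicate(10, {
    G <- simulate_genotypes(150, 200)
    K <- kinship_from_genotypes(G)
    M <- setNames(rnorm(150), rownames(G$dosages))
    fit <- he_fit(zscore(M), NULL, K)
    abs(fit$beta) < 3 * fit$se
  })
  expect_gte(sum(ok), 8)
})

test_that("heritability is half the slope with matching standard errors", {
  K <- toy_kinship(8, 108)
  set.seed(109)
  M <- zscore(named_rnorm(8))
  fit <- he_fit(M, NULL, K)
  est <- he_h2(M, K)
  expect_identical(est$h2, fit$beta / 2)
  expect_identical(est$se_raw, fit$se / 2)
  expect_equal(est$se_corrected,
               est$se_raw * correction_factor(min(max(est$h2, 0), 1), 8))
})

test_that("the correction factor carries the derived coefficients", {
  cc <- correction_coefficients()
  expect_identical(cc$slope_h2, 0.020225)
  expect_identical(cc$slope_const, 0.004225)
  expect_identical(cc$int_h2, -0.2352)
  expect_identical(cc$int_const, 0.9467)
  expect_equal(correction_factor(0.4, 900), 1.22207, tolerance = 1e-6)
  # strictly increasing with n at fixed h2
  Fs <- vapply(c(100, 400, 1600, 6400), correction_factor, numeric(1),
               h2 = 0.4)
  expect_true(all(diff(Fs) > 0))
  # h2 outside [0,1] is clipped, not an error
  expect_equal(correction_factor(1.4, 900), correction_factor(1, 900))
  expect_equal(correction_factor(-0.2, 900), correction_factor(0, 900))
})

test_that("delta_norm is a standardized antisymmetric difference", {
  mk <- function(h2, se) structure(list(h2 = h2, se_corrected = se,
                                        se_raw = se), class = "he_estimate")
  expect_equal(delta_norm(mk(0.5, 0.1), mk(0.3, 0.1)), 0.2 / sqrt(0.02),
               tolerance = 1e-12)
  expect_equal(delta_norm(mk(0.5, 0.1), mk(0.3, 0.1)), 1.41421,
               tolerance = 1e-5)
  expect_equal(delta_norm(mk(0.4, 0.1), mk(0.4, 0.1)), 0)
  expect_equal(delta_norm(mk(0.5, 0.1), mk(0.3, 0.1)),
               -delta_norm(mk(0.3, 0.1), mk(0.5, 0.1)))
  expect_error(delta_norm(mk(0.4, 0), mk(0.4, 0)), "variance")
  # scaling the SEs by 10 scales delta_norm (hence sigma) by 1/10
  expect_equal(delta_norm(mk(0.5, 1), mk(0.3, 1)),
               delta_norm(mk(0.5, 0.1), mk(0.3, 0.1)) / 10)
})

test_that("correction coefficients round-trip through two-stage regression", {
  tab <- expand.grid(h2 = c(0.1, 0.2, 0.4, 0.8, 0.99),
                     n = c(220, 500, 1000, 2000, 5000))
  cc0 <- correction_coefficients()
  tab$sigma_delta_norm <- sqrt(tab$n) * (cc0$slope_h2 * tab$h2 + cc0$slope_const) +
    (cc0$int_h2 * tab$h2 + cc0$int_const)
  cc <- derive_correction_coefficients(tab)
  expect_equal(cc$slope_h2, cc0$slope_h2, tolerance = 1e-8)
  expect_equal(cc$slope_const, cc0$slope_const, tolerance = 1e-8)
  expect_equal(cc$int_h2, cc0$int_h2, tolerance = 1e-8)
  expect_equal(cc$int_const, cc0$int_const, tolerance = 1e-8)

  # flat table: no n or h2 dependence, unit intercept
  flat <- expand.grid(h2 = c(0.1, 0.4, 0.8), n = c(250, 1000, 4000))
  flat$sigma_delta_norm <- 1
  ccf <- derive_correction_coefficients(flat)
  expect_equal(ccf$slope_h2, 0, tolerance = 1e-12)
  expect_equal(ccf$slope_const, 0, tolerance = 1e-12)
  expect_equal(ccf$int_h2, 0, tolerance = 1e-12)
  expect_equal(ccf$int_const, 1, tolerance = 1e-12)

  # small noise perturbs the recovery only slightly
  set.seed(110)
  tab$sigma_delta_norm <- tab$sigma_delta_norm + rnorm(nrow(tab), sd = 1e-3)
  ccn <- derive_correction_coefficients(tab)
  expect_equal(ccn$slope_h2, cc0$slope_h2, tolerance = 1e-2)
  expect_equal(ccn$int_const, cc0$int_const, tolerance = 1e-1)

  expect_error(derive_correction_coefficients(
    data.frame(h2 = 0.4, n = c(100, 200), sigma_delta_norm = 1)),
    "two h2 levels")
})

test_that("trait and rg filters apply the published rules", {
  mk <- function(h2, se) structure(list(h2 = h2, se_corrected = se,
                                        se_raw = se), class = "he_estimate")
  res <- filter_traits(list(a = mk(0.05, 0.02), b = mk(1.2, 0.1),
                            c = mk(1.05, 0.10), d = mk(0.45, 0.05)))
  expect_identical(res$keep, c(FALSE, FALSE, TRUE, TRUE))
  expect_match(res$reason[1], "h2 < 0.1")
  expect_match(res$reason[2], "1 \\+ SE")

  expect_false(filter_rg(1.3, 0.1))
  expect_true(filter_rg(1.05, 0.1))
  expect_true(filter_rg(0, 0.001))
  expect_false(filter_rg(-1.3, 0.1))
  expect_true(filter_rg(-1.05, 0.1))
})

test_that("genetic correlation of a trait with itself is exactly 1", {
  set.seed(111)
  G <- simulate_genotypes(200, 300)
  tr <- simulate_trait(G, 0.5, 10)
  K <- kinship_from_genotypes(G)
  M <- zscore(tr$values)
  est <- he_rg(M, M, K)
  expect_equal(est$rg, 1, tolerance = 1e-12)
  expect_equal(est$rho, est$h2_M, tolerance = 1e-12)
})

test_that("rg is symmetric in its arguments and guards non-positive h2", {
  set.seed(112)
  G <- simulate_genotypes(250, 300)
  pr <- simulate_correlated_pair(G, 0.5, 0.5, 0.6, n_causal = 50)
  K <- kinship_from_genotypes(G)
  M <- zscore(pr$M$values); N <- zscore(pr$N$values)
  ab <- he_rg(M, N, K)
  ba <- he_rg(N, M, K)
  expect_equal(ab$rg, ba$rg, tolerance = 1e-10)
  expect_equal(ab$se, ba$se, tolerance = 1e-10)
  # structural relation rg = rho / sqrt(h2_M h2_N)
  expect_equal(ab$rg, ab$rho / sqrt(ab$h2_M * ab$h2_N), tolerance = 1e-12)

  # a pure-noise trait has h2 <= 0 often; force the guard deterministically
  fake <- structure(list(h2 = -0.02, se_raw = 0.05, se_corrected = 0.05,
                         n_animals = 250), class = "he_estimate")
  okM <- he_h2(M, K)
  res <- he_rg(M, N, K, okM, fake)
  expect_false(res$estimable)
  expect_false(res$valid)
  expect_true(is.na(res$rg))
})

test_that("estimate precision improves with cohort size", {
  set.seed(113)
  sds <- vapply(c(250, 1000), function(n) {
    sd(replicate(20, {
      G <- simulate_genotypes(n, 400)
      tr <- simulate_trait(G, 0.4, 10)
      he_h2(zscore(tr$values), kinship_from_genotypes(G))$h2
    }))
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})
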