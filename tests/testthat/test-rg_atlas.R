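test_that("Bonferroni arithmetic over unordered trait pairs", {
  bf <- bonferroni_threshold(7233)
  expect_identical(bf$n_pairs, 26154528)
  expect_equal(signif(bf$threshold, 4), 1.912e-9)
  expect_equal(bonferroni_threshold(2)$threshold, 0.05)
})

test_that("r_pg equals a hand-computed Pearson on z-scored rg vectors", {
  rg <- matrix(c(1,    0.8,  0.1, -0.3, 0.5,
                 0.8,  1,    0.2, -0.1, 0.4,
                 0.1,  0.2,  1,    0.7, -0.2,
                 -0.3, -0.1, 0.7,  1,   -0.5,
                 0.5,  0.4, -0.2, -0.5, 1), 5, 5,
               dimnames = list(letters[1:5], letters[1:5]))
  res <- rpg_matrix(rg)
  # independent evaluation: explicit z-scoring and masking loops
  Z <- rg
  diag(Z) <- NA
  Z <- apply(Z, 2, function(v) (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE))
  for (a in 1:4) {
    for (b in (a + 1):5) {
      use <- setdiff(1:5, c(a, b))
      expect_equal(res$rpg[a, b], cor(Z[use, a], Z[use, b]),
                   tolerance = 1e-12)
      expect_equal(res$n_obs[a, b], length(use))
    }
  }
  expect_equal(diag(res$rpg), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(abs(res$rpg) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(isSymmetric(res$rpg))
})

test_that("masked rg entries are excluded pairwise from r_pg", {
  set.seed(121)
  rg <- cor(matrix(rnorm(80), 10, 8))
  dimnames(rg) <- list(letters[1:8], letters[1:8])
  rg[2, 5] <- rg[5, 2] <- NA
  res <- rpg_matrix(rg)
  expect_equal(res$n_obs[2, 3], 8 - 2 - 1)  # loses the masked entry too
  expect_false(anyNA(res$rpg[1, ]))
})

test_that("distance transform is exact and order-preserving", {
  expect_equal(rpg_to_distance(1, 50), 0)
  expect_equal(rpg_to_distance(-1, 50), 0)
  expect_equal(rpg_to_distance(0, 100), sqrt(200))
  expect_equal(rpg_to_distance(0, 100), 14.1421, tolerance = 1e-4)
  d <- vapply(c(0, 0.3, 0.6, 0.9), rpg_to_distance, numeric(1), n_obs = 80)
  expect_true(all(diff(d) < 0))
  expect_error(rpg_to_distance(1.2, 10), "exceed")
})

test_that("Ward clustering recovers well-separated planted groups", {
  set.seed(122)
  n <- 12
  D <- matrix(9 + runif(n * n), n, n)  # between-group distances ~9-10
  grp <- rep(1:2, each = 6)
  for (g in 1:2) {
    idx <- which(grp == g)
    D[idx, idx] <- 0.5 + runif(36) * 0.2  # within-group ~0.5-0.7
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  dend <- ward_cluster(D)
  expect_s3_class(dend, "hclust")
  expect_equal(nrow(dend$merge), n - 1)
  cut2 <- cutree(dend, 2)
  expect_equal(length(unique(tapply(grp, cut2, function(x) paste(unique(x))))), 2)
  # first merge joins the globally closest pair
  closest <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  expect_setequal(-dend$merge[1, ], unname(closest))
  expect_error(ward_cluster(D + diag(n)), "zero diagonal")
  Dbad <- D; Dbad[1, 2] <- Inf; Dbad[2, 1] <- Inf
  expect_error(ward_cluster(Dbad), "finite")
})

test_that("heritability ratio follows its definition", {
  expect_equal(h2_ratio(0.4, 0.4, 0.4), 1)
  expect_equal(h2_ratio(0.6, 0.4, 0.4), 1.5)
  expect_true(is.na(h2_ratio(0.3, -0.2, 0.2)))
  expect_true(is.na(h2_ratio(0.3, 0, 0)))
})

test_that("meta-trait construction sign-aligns members to the focal trait", {
  set.seed(123)
  n <- 80
  base <- rnorm(n)
  Y <- cbind(t1 = zscore(base + rnorm(n, sd = 0.2)),
             t2 = zscore(-base + rnorm(n, sd = 0.2)))
  rownames(Y) <- sprintf("m%03d", 1:n)

  # singleton cluster: identity up to z-scoring
  single <- build_meta_trait(Y[, 1, drop = FALSE], 0.5)
  expect_equal(unname(single$values), unname(zscore(Y[, 1])), tolerance = 1e-12)

  # exact negation: the flipped member equals the focal member
  Y2 <- cbind(t1 = Y[, 1], t2 = -Y[, 1])
  mt <- build_meta_trait(Y2, c(0.5, 0.4), matrix(c(1, -1, -1, 1), 2, 2))
  expect_identical(mt$signs, c(1, -1))
  expect_equal(unname(mt$values), unname(zscore(Y2[, 1])), tolerance = 1e-12)

  # without flipping the pair averages to ~0 variance; flipping restores it
  raw_mean <- rowMeans(Y2)
  expect_lt(var(raw_mean), 1e-20)
  flipped_mean <- rowMeans(sweep(Y2, 2, c(1, -1), "*"))
  expect_equal(var(flipped_mean), var(Y2[, 1]), tolerance = 1e-12)

  # individuals with no member data become missing
  Y3 <- Y
  Y3[5, ] <- NA
  mt3 <- build_meta_trait(Y3, c(0.5, 0.4), matrix(c(1, -1, -1, 1), 2, 2))
  expect_true(is.na(mt3$values[5]))
  expect_error(build_meta_trait(Y[, 0], numeric(0)), "empty")
})

test_that("averaging noisy copies of one genetic signal raises meta h2", {
  set.seed(124)
  G <- simulate_genotypes(600, 400)
  K <- kinship_from_genotypes(G)
  h2_at_G <- vapply(c(1, 2, 4, 8), function(g) {
    mean(replicate(4, {
      tr <- simulate_trait(G, 1, 10)  # pure genetic signal
      gval <- tr$genetic_values
      vg <- var(gval)
      copies <- vapply(seq_len(g), function(i)
        zscore(gval + rnorm(600, sd = sqrt(vg * 0.7 / 0.3))), numeric(600))
      rownames(copies) <- names(gval)
      mt <- build_meta_trait(copies, rep(0.3, g))
      he_h2(mt$values, K)$h2
    }))
  }, numeric(1))
  # h2 = 0.3 per copy; averaging independent noise raises the fraction
  expect_true(all(diff(h2_at_G) > -0.05))  # monotone up to noise
  expect_gt(h2_at_G[2], h2_at_G[1])        # two copies beat one
  expect_gt(h2_at_G[4], h2_at_G[1] + 0.2)  # eight copies are far better
})

test_that("sweep_k evaluates the h2-ratio curve over dendrogram cuts", {
  set.seed(125)
  G <- simulate_genotypes(300, 600)
  blocks <- simulate_trait_blocks(G, 3, 4, h2 = 0.5, rg_within = 0.9,
                                  n_causal = 10)
  K <- kinship_from_genotypes(G)
  Y <- apply(blocks$values, 2, zscore)
  R <- rg_matrix(Y, K)
  rpg <- rpg_matrix(R)
  D <- rpg_to_distance(rpg$rpg, rpg$n_obs)
  dend <- ward_cluster(D)
  h2v <- vapply(colnames(Y), function(t) R$h2_estimates[[t]]$h2, numeric(1))
  sol <- sweep_k(dend, Y, K, k_range = 2:8, h2 = h2v, rpg = rpg$rpg)
  expect_s3_class(sol, "cluster_solution")
  expect_equal(nrow(sol$curve), 7)
  # cutting at the planted block count recovers the blocks exactly
  tab <- table(cutree(dend, 3), blocks$blocks)
  expect_true(all(colSums(tab > 0) == 1))
  # merging unrelated blocks (k < B) hurts relative to the pure-block cut
  curve <- sol$curve
  expect_gt(curve$mean_h2_ratio[curve$k == 3],
            curve$mean_h2_ratio[curve$k == 2])
  # pure-block clusters benefit from aggregation: ratio > 1
  expect_gt(curve$mean_h2_ratio[curve$k == 3], 1)
  # the chosen cut maximizes the curve, smallest k on ties
  expect_equal(sol$k,
               curve$k[which.max(curve$mean_h2_ratio)])
})

test_that("cluster summary reports partition arithmetic", {
  cs <- cluster_summary(rep(1:383, length.out = 1898))
  expect_equal(cs$n_traits, 1898)
  expect_equal(cs$n_clusters, 383)
  expect_equal(round(cs$mean_size, 2), 4.96)
})

test_that("intra-trait rg across disjoint cohorts recovers shared genetics", {
  set.seed(126)
  G <- simulate_genotypes(500, 600)
  K <- kinship_from_genotypes(G)
  ids <- rownames(G$dosages)
  sp <- split_half(ids, seed = 127)
  mk_trait <- function(shared_g, extra_noise) {
    lapply(sp, function(half) {
      g <- shared_g[half]
      zscore(g + rnorm(length(half), sd = sqrt(var(g) * extra_noise)))
    })
  }
  # identical genetics in both cohorts at moderate noise
  traits <- lapply(1:3, function(i) {
    tr <- simulate_trait(G, 1, 10)
    gr <- mk_trait(tr$genetic_values, 1)
    names(gr) <- c("year1", "year2")
    gr
  })
  names(traits) <- paste0("trait", 1:3)
  res <- group_rg_summary(traits, K)
  expect_true(all(res$summary$n_traits <= 3))
  expect_lt(abs(res$summary$mean_rg - 1),
            2 * max(res$summary$se_mean, 0.25))
  # only valid estimates enter the summary
  expect_equal(sum(res$per_trait$valid), sum(res$summary$n_traits))

  # genetically unrelated group effects give rg near zero
  set.seed(128)
  null_traits <- lapply(1:3, function(i) {
    tr1 <- simulate_trait(G, 1, 10)
    tr2 <- simulate_trait(G, 1, 10)
    list(year1 = zscore(tr1$genetic_values[sp$first] +
                          rnorm(length(sp$first), sd = sd(tr1$genetic_values))),
         year2 = zscore(tr2$genetic_values[sp$second] +
                          rnorm(length(sp$second), sd = sd(tr2$genetic_values))))
  })
  names(null_traits) <- paste0("null", 1:3)
  res0 <- group_rg_summary(null_traits, K)
  expect_lt(abs(res0$summary$mean_rg), 0.6)
})
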