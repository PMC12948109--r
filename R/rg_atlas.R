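#' Phenome-wide Bonferroni threshold
#'
#' Significance threshold for all unordered trait pairs:
#' `alpha / (T (T - 1) / 2)`.
#'
#' @param n_traits Number of traits `T`.
#' @param alpha Family-wise error rate, default 0.05.
#' @return List with `n_pairs` and `threshold`.
#' @examples
#' bonferroni_threshold(7233)  # 26,154,528 pairs, threshold 1.912e-9
#' @export
bonferroni_threshold <- function(n_traits, alpha = 0.05) {
  n_pairs <- n_traits * (n_traits - 1) / 2
  list(n_pairs = n_pairs, threshold = alpha / n_pairs)
}

#' Pairwise genetic-correlation matrix
#'
#' Estimates [he_rg()] for every unordered pair of traits measured on a
#' common cohort, together with the phenome-wide Bonferroni threshold.
#' Failed or non-estimable pairs are masked, not fatal.
#'
#' @param Y Individuals x traits matrix of z-normalized values (colnames
#'   are trait names, rownames individual IDs).
#' @param K Kinship matrix.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param coefficients Optional correction-coefficient override.
#' @return Object of class `"rg_matrix"`: symmetric matrices `rg`, `se`,
#'   `p`, logical `valid`, per-trait `h2_estimates`, `threshold`,
#'   `n_pairs`, `alpha`. Diagonals are 1 (rg) / TRUE (valid).
#' @export
rg_matrix <- function(Y, K, alpha = 0.05, coefficients = NULL) {
  T_ <- ncol(Y)
  traits <- colnames(Y)
  ests <- lapply(seq_len(T_), function(t)
    tryCatch(he_h2(Y[, t], K, coefficients), error = function(e) NULL))
  names(ests) <- traits
  mk <- function(fill) matrix(fill, T_, T_, dimnames = list(traits, traits))
  rg <- mk(NA_real_); se <- mk(NA_real_); p <- mk(NA_real_)
  valid <- mk(FALSE)
  diag(rg) <- 1; diag(valid) <- TRUE
  for (i in seq_len(T_ - 1)) {
    for (j in (i + 1):T_) {
      if (is.null(ests[[i]]) || is.null(ests[[j]])) next
      est <- tryCatch(
        he_rg(Y[, i], Y[, j], K, ests[[i]], ests[[j]],
              coefficients = coefficients),
        error = function(e) NULL)
      if (is.null(est) || !est$estimable) next
      rg[i, j] <- rg[j, i] <- est$rg
      se[i, j] <- se[j, i] <- est$se
      p[i, j] <- p[j, i] <- est$p
      valid[i, j] <- valid[j, i] <- est$valid
    }
  }
  bf <- bonferroni_threshold(T_, alpha)
  structure(list(rg = rg, se = se, p = p, valid = valid,
                 h2_estimates = ests, threshold = bf$threshold,
                 n_pairs = bf$n_pairs, alpha = alpha),
            class = "rg_matrix")
}

#' Pearson correlations of genetic-correlation vectors
#'
#' The similarity used for trait clustering: for each pair of traits the
#' Pearson correlation of their z-score-normalized vectors of genetic
#' correlations across the whole atlas. Each trait's r_g vector is z-scored
#' over its finite, valid off-diagonal entries; for a pair (a, b) the two
#' traits' mutual and self entries are excluded and the correlation is
#' taken over the remaining shared finite entries. Cells with fewer than 3
#' shared entries are masked.
#'
#' @param R An `"rg_matrix"` object, or a plain symmetric matrix of r_g
#'   values (then `valid` defaults to all finite entries).
#' @return Object of class `"rpg_matrix"`: list with `rpg` (values in
#'   \[-1, 1\], unit diagonal) and `n_obs` (shared entries per cell).
#' @export
rpg_matrix <- function(R) {
  if (inherits(R, "rg_matrix")) {
    rg <- R$rg
    ok <- R$valid & is.finite(R$rg)
  } else {
    rg <- as.matrix(R)
    ok <- is.finite(rg)
  }
  T_ <- ncol(rg)
  if (T_ < 3) stop("need at least 3 traits")
  diag(ok) <- FALSE  # self entries are not informative about sharing
  Z <- rg
  Z[!ok] <- NA_real_
  Z <- apply(Z, 2, function(col) {
    f <- is.finite(col)
    col[f] <- (col[f] - mean(col[f])) / stats::sd(col[f])
    col
  })
  rpg <- matrix(NA_real_, T_, T_, dimnames = dimnames(rg))
  n_obs <- matrix(0L, T_, T_, dimnames = dimnames(rg))
  diag(rpg) <- 1
  for (a in seq_len(T_ - 1)) {
    for (b in (a + 1):T_) {
      use <- is.finite(Z[, a]) & is.finite(Z[, b])
      use[c(a, b)] <- FALSE
      m <- sum(use)
      n_obs[a, b] <- n_obs[b, a] <- m
      if (m < 3) next
      rpg[a, b] <- rpg[b, a] <- stats::cor(Z[use, a], Z[use, b])
    }
  }
  structure(list(rpg = rpg, n_obs = n_obs), class = "rpg_matrix")
}

#' Distance transform of Pearson genetic correlations
#'
#' Converts |r_pg| to a Euclidean-scale distance,
#' `d = sqrt(2 n (1 - |r_pg|))` (the non-negative algebraic form of
#' `sqrt(-2 n (|r_pg| - 1))`). The absolute value is used because positive
#' and negative genetic correlations both indicate a shared genetic basis.
#'
#' @param rpg Correlation value(s) in \[-1, 1\] (scalar or matrix).
#' @param n_obs Number of observations behind each correlation (scalar or
#'   matrix conforming to `rpg`).
#' @return Distance(s) on the same shape as `rpg`.
#' @export
rpg_to_distance <- function(rpg, n_obs) {
  if (any(abs(rpg) > 1 + 1e-12, na.rm = TRUE))
    stop("|rpg| must not exceed 1")
  d <- sqrt(2 * n_obs * pmax(1 - abs(rpg), 0))
  if (is.matrix(d)) diag(d) <- 0
  d
}

#' Ward hierarchical clustering of a trait distance matrix
#'
#' Agglomerative clustering with the Ward-D2 criterion (squared-distance
#' variance update) on a symmetric, zero-diagonal distance matrix.
#'
#' @param D Symmetric distance matrix with zero diagonal; all finite.
#' @return An [stats::hclust] dendrogram.
#' @export
ward_cluster <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix must have zero diagonal")
  if (any(!is.finite(D))) stop("non-finite distances")
  stats::hclust(stats::as.dist(D), method = "ward.D2")
}

#' Meta-trait heritability ratio
#'
#' `h2_meta / (0.5 * (h2_sub1 + h2_sub2))`: the heritability of an
#' aggregated meta-trait relative to the mean heritability of its two
#' child sub-clusters. Ratios with a non-positive denominator are
#' undefined (`NA`) and excluded from means.
#'
#' @param h2_meta Heritability of the combined meta-trait.
#' @param h2_sub1,h2_sub2 Heritabilities of the two sub-cluster
#'   meta-traits.
#' @return The ratio, or `NA` when the denominator is non-positive.
#' @export
h2_ratio <- function(h2_meta, h2_sub1, h2_sub2) {
  denom <- 0.5 * (h2_sub1 + h2_sub2)
  ifelse(is.finite(denom) & denom > 0, h2_meta / denom, NA_real_)
}

#' Construct a meta-trait from a cluster of phenotypes
#'
#' The focal member is the trait with the highest heritability; members
#' whose Pearson genetic correlation with the focal trait is negative are
#' sign-flipped, then the per-individual mean over available sign-adjusted
#' members is taken and re-z-scored (so the HE identity `h2 = beta / 2`
#' remains applicable). Individuals without any member measurement are
#' missing.
#'
#' @param Y Individuals x members matrix of z-normalized member traits.
#' @param h2 Per-member heritability estimates (defines the focal member).
#' @param rpg Optional members x members r_pg matrix (or a vector of r_pg
#'   against the focal member); missing values default to a positive sign.
#' @return Object of class `"meta_trait"`: `values` (named, z-scored),
#'   `members`, `signs`, `focal`.
#' @export
build_meta_trait <- function(Y, h2, rpg = NULL) {
  Y <- as.matrix(Y)
  if (ncol(Y) == 0) stop("empty cluster")
  if (ncol(Y) != length(h2)) stop("one h2 per member required")
  focal <- which.max(h2)
  signs <- rep(1, ncol(Y))
  if (!is.null(rpg) && ncol(Y) > 1) {
    r_focal <- if (is.matrix(rpg)) rpg[, focal] else rpg
    signs <- ifelse(!is.na(r_focal) & r_focal < 0, -1, 1)
    signs[focal] <- 1
  }
  adj <- sweep(Y, 2, signs, "*")
  vals <- rowMeans(adj, na.rm = TRUE)
  vals[rowSums(is.finite(adj)) == 0] <- NA_real_
  structure(list(values = zscore(vals),
                 members = colnames(Y), signs = signs,
                 focal = if (!is.null(colnames(Y))) colnames(Y)[focal]
                         else focal),
            class = "meta_trait")
}

# Leaf sets of every internal node of an hclust tree, as sorted integer
# vectors, plus the two child leaf sets per node.
.node_leafsets <- function(hc) {
  nm <- nrow(hc$merge)
  sets <- vector("list", nm)
  children <- vector("list", nm)
  for (i in seq_len(nm)) {
    kids <- lapply(hc$merge[i, ], function(v)
      if (v < 0) -v else sets[[v]])
    sets[[i]] <- sort(c(kids[[1]], kids[[2]]))
    children[[i]] <- lapply(kids, sort)
  }
  list(sets = sets, children = children)
}

#' Choose the cluster count that maximizes the mean heritability ratio
#'
#' For each candidate `k` the dendrogram is cut into `k` clusters; each
#' multi-member cluster's meta-trait and the meta-traits of its two child
#' sub-dendrograms are built and their heritabilities estimated by HE
#' regression; the per-cluster [h2_ratio()]s are averaged (singleton
#' clusters and clusters with a non-positive denominator are excluded from
#' the mean). The returned `k` maximizes that mean; ties favor the
#' smallest `k`.
#'
#' @param dend [stats::hclust] tree whose labels match columns of `Y`.
#' @param Y Individuals x traits matrix of z-normalized phenotypes.
#' @param K Kinship matrix.
#' @param k_range Candidate cluster counts (default `2:(T - 1)`).
#' @param h2 Optional named per-trait heritabilities (estimated when
#'   omitted).
#' @param rpg Optional `"rpg_matrix"` object or plain r_pg matrix for
#'   sign-flipping in meta-trait construction.
#' @param coefficients Optional correction-coefficient override.
#' @return Object of class `"cluster_solution"`: `k`, `assignments` (at
#'   the chosen `k`), `curve` (data frame `k`, `mean_h2_ratio`,
#'   `n_clusters_used`), `summary` (see [cluster_summary()]).
#' @export
sweep_k <- function(dend, Y, K, k_range = NULL, h2 = NULL, rpg = NULL,
                    coefficients = NULL) {
  stopifnot(inherits(dend, "hclust"))
  traits <- dend$labels
  if (is.null(traits)) traits <- colnames(Y)
  if (!all(traits %in% colnames(Y)))
    stop("phenotypes missing for some dendrogram leaves")
  Y <- Y[, traits, drop = FALSE]
  T_ <- length(traits)
  if (is.null(k_range)) k_range <- 2:(T_ - 1)
  if (is.null(h2)) {
    h2 <- vapply(traits, function(t)
      he_h2(Y[, t], K, coefficients)$h2, numeric(1))
  } else h2 <- h2[traits]
  rpg_m <- if (inherits(rpg, "rpg_matrix")) rpg$rpg else rpg
  nodes <- .node_leafsets(dend)
  sigs <- vapply(nodes$sets, paste, character(1), collapse = ",")
  meta_h2 <- function(members) {
    mt <- build_meta_trait(Y[, members, drop = FALSE], h2[members],
                           if (!is.null(rpg_m))
                             rpg_m[members, members, drop = FALSE])
    he_h2(mt$values, K, coefficients)$h2
  }
  curve <- data.frame(k = k_range, mean_h2_ratio = NA_real_,
                      n_clusters_used = 0L)
  assignments_by_k <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    asg <- stats::cutree(dend, k = k)
    ratios <- c()
    for (cl in unique(asg)) {
      members <- which(asg == cl)
      if (length(members) < 2) next  # singletons have no two children
      node <- match(paste(sort(members), collapse = ","), sigs)
      if (is.na(node)) next
      kids <- nodes$children[[node]]
      hm <- meta_h2(traits[members])
      hs1 <- meta_h2(traits[kids[[1]]])
      hs2 <- meta_h2(traits[kids[[2]]])
      ratios <- c(ratios, h2_ratio(hm, hs1, hs2))
    }
    ratios <- ratios[is.finite(ratios)]
    curve$n_clusters_used[ki] <- length(ratios)
    if (length(ratios) > 0) curve$mean_h2_ratio[ki] <- mean(ratios)
    assignments_by_k[[ki]] <- asg
  }
  best <- which.max(curve$mean_h2_ratio)  # first index wins ties: smallest k
  structure(list(k = curve$k[best],
                 assignments = assignments_by_k[[best]],
                 curve = curve,
                 summary = cluster_summary(assignments_by_k[[best]])),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution: k = %d (mean h2 ratio %.3f); %d traits, mean %.2f traits/cluster\n",
              x$k, x$curve$mean_h2_ratio[x$curve$k == x$k],
              x$summary$n_traits, x$summary$mean_size))
  invisible(x)
}

#' Summary of a trait-cluster partition
#'
#' @param assignments Named vector mapping traits to cluster IDs.
#' @return List with `n_traits`, `n_clusters`, `mean_size`, `median_size`.
#' @examples
#' cluster_summary(rep(1:383, length.out = 1898))$mean_size  # 4.96
#' @export
cluster_summary <- function(assignments) {
  sizes <- table(assignments)
  list(n_traits = length(assignments), n_clusters = length(sizes),
       mean_size = length(assignments) / length(sizes),
       median_size = stats::median(as.integer(sizes)))
}

#' Intra-trait genetic correlations across measurement groups
#'
#' For traits measured repeatedly across disjoint cohort groups (time
#' points, dietary groups), estimates the genetic correlation of each
#' trait between every pair of groups, drops estimates outside the
#' `|rg| <= 1 + se` validity band, and summarizes the mean and standard
#' error of intra-trait r_g per group pair across traits.
#'
#' @param traits Named list over traits; each element a named list over
#'   groups of named, z-normalized trait vectors (disjoint animal sets).
#' @param K Kinship matrix covering all animals.
#' @param coefficients Optional correction-coefficient override.
#' @return List with `per_trait` (data frame: `trait`, `group1`, `group2`,
#'   `rg`, `se`, `valid`) and `summary` (data frame: `group1`, `group2`,
#'   `mean_rg`, `se_mean`, `n_traits` — valid estimates only).
#' @export
group_rg_summary <- function(traits, K, coefficients = NULL) {
  rows <- list()
  for (tn in names(traits)) {
    groups <- traits[[tn]]
    gn <- names(groups)
    if (length(gn) < 2) stop("trait '", tn, "' has fewer than 2 groups")
    for (i in seq_len(length(gn) - 1)) {
      for (j in (i + 1):length(gn)) {
        est <- tryCatch(
          he_rg(groups[[i]], groups[[j]], K, coefficients = coefficients),
          error = function(e) NULL)
        if (is.null(est) || !est$estimable) next
        rows[[length(rows) + 1]] <- data.frame(
          trait = tn, group1 = gn[i], group2 = gn[j],
          rg = est$rg, se = est$se, valid = est$valid,
          stringsAsFactors = FALSE)
      }
    }
  }
  per_trait <- do.call(rbind, rows)
  if (is.null(per_trait)) stop("no estimable group pairs")
  ok <- per_trait[per_trait$valid, , drop = FALSE]
  agg <- lapply(split(ok, paste(ok$group1, ok$group2, sep = "\r")),
                function(d) data.frame(
                  group1 = d$group1[1], group2 = d$group2[1],
                  mean_rg = mean(d$rg),
                  se_mean = stats::sd(d$rg) / sqrt(nrow(d)),
                  n_traits = nrow(d), stringsAsFactors = FALSE))
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  list(per_trait = per_trait, summary = summary)
}
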