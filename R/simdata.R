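#' Simulate unlinked diploid SNP genotypes
#'
#' Draws biallelic dosages for a cohort of outbred individuals at unlinked
#' markers. Each marker is assigned a minor allele frequency sampled from
#' `maf_pool` and dosages are drawn as two independent binomial allele draws,
#' so markers are mutually independent (no linkage disequilibrium).
#'
#' @param n_individuals Number of individuals.
#' @param n_markers Number of unlinked markers.
#' @param maf_pool Numeric vector of allele frequencies in (0, 0.5] from which
#'   each marker's frequency is sampled (with replacement). Defaults to the
#'   frequencies used throughout the package's calibration simulations.
#' @param seed Optional integer seed; the same seed reproduces the matrix
#'   bitwise.
#' @param n_chr Number of chromosomes over which markers are laid out.
#' @param map_length Position span per chromosome in Mb; markers are placed
#'   uniformly.
#' @return An object of class `"geno_sim"`: a list with `dosages`
#'   (individuals x markers integer matrix in \{0,1,2\}, rownames are
#'   individual IDs), `mafs` (seeded per-marker allele frequency) and `map`
#'   (data frame with `marker`, `chr`, `pos`).
#' @examples
#' G <- simulate_genotypes(100, 50, seed = 1)
#' range(G$dosages)
#' @export
simulate_genotypes <- function(n_individuals, n_markers,
                               maf_pool = c(0.05, 0.1, 0.3, 0.4),
                               seed = NULL, n_chr = 1, map_length = 100) {
  if (n_individuals < 1 || n_markers < 1)
    stop("need at least one individual and one marker")
  if (any(maf_pool <= 0 | maf_pool > 0.5))
    stop("all allele frequencies in 'maf_pool' must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  mafs <- sample(maf_pool, n_markers, replace = TRUE)
  X <- matrix(stats::rbinom(n_individuals * n_markers, 2L,
                            rep(mafs, each = n_individuals)),
              nrow = n_individuals, ncol = n_markers)
  ids <- sprintf("ind%05d", seq_len(n_individuals))
  markers <- sprintf("m%05d", seq_len(n_markers))
  dimnames(X) <- list(ids, markers)
  chr <- rep(seq_len(n_chr), length.out = n_markers)
  chr <- sort(chr)
  pos <- unlist(lapply(split(seq_len(n_markers), chr), function(ix)
    seq(0, map_length, length.out = length(ix) + 2L)[-c(1L, length(ix) + 2L)]),
    use.names = FALSE)
  map <- data.frame(marker = markers, chr = chr, pos = pos,
                    stringsAsFactors = FALSE)
  structure(list(dosages = X, mafs = stats::setNames(mafs, markers), map = map),
            class = "geno_sim")
}

#' @export
print.geno_sim <- function(x, ...) {
  cat("Simulated genotypes:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "markers on", length(unique(x$map$chr)),
      "chromosome(s)\n")
  invisible(x)
}

# Standardize dosages by the seeded allele frequency:
# z = (dosage - 2p) / sqrt(2 p (1 - p)).
standardize_dosages <- function(G, markers = seq_along(G$mafs)) {
  p <- G$mafs[markers]
  sweep(sweep(G$dosages[, markers, drop = FALSE], 2, 2 * p, "-"),
        2, sqrt(2 * p * (1 - p)), "/")
}

#' Simulate an additive trait with known heritability
#'
#' Selects `n_causal` markers at random, draws independent normal effect
#' sizes, builds the genetic value as the effect-weighted sum of standardized
#' dosages, and adds independent Gaussian noise scaled against the *realized*
#' variance of the genetic values so that the realized heritability of the
#' cohort matches `h2` closely in every replicate.
#'
#' @param G A `"geno_sim"` object from [simulate_genotypes()].
#' @param h2 Target narrow-sense heritability in \[0, 1\].
#' @param n_causal Number of causal markers (default 10).
#' @param seed Optional integer seed.
#' @return An object of class `"sim_trait"`: list with `values` (named
#'   per-individual trait values), `genetic_values`, `causal_indices`,
#'   `causal_effects` and `true_h2`.
#' @examples
#' G <- simulate_genotypes(500, 200, seed = 2)
#' tr <- simulate_trait(G, h2 = 0.4, seed = 3)
#' var(tr$genetic_values) / var(tr$values)  # close to 0.4
#' @export
simulate_trait <- function(G, h2, n_causal = 10, seed = NULL) {
  stopifnot(inherits(G, "geno_sim"))
  if (h2 < 0 || h2 > 1) stop("'h2' must lie in [0, 1]")
  m <- ncol(G$dosages)
  if (n_causal > m) stop("'n_causal' exceeds the number of markers")
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(m, n_causal))
  eff <- stats::rnorm(n_causal)
  g <- drop(standardize_dosages(G, idx) %*% eff)
  y <- .add_noise(g, h2, nrow(G$dosages))
  names(y) <- rownames(G$dosages)
  structure(list(values = y, genetic_values = stats::setNames(g, names(y)),
                 causal_indices = idx, causal_effects = eff, true_h2 = h2),
            class = "sim_trait")
}

# Add environmental noise calibrated to the realized genetic variance so that
# var(g)/var(y) ~ h2.  h2 = 0 yields pure standard-normal noise; h2 = 1
# returns the genetic values untouched.
.add_noise <- function(g, h2, n) {
  if (h2 == 0) return(stats::rnorm(n))
  if (h2 == 1) return(g)
  vg <- stats::var(g)
  g + stats::rnorm(n, sd = sqrt(vg * (1 - h2) / h2))
}

#' Simulate a pleiotropic trait pair with known genetic correlation
#'
#' Both traits share a single causal marker set; their per-marker effect
#' sizes are drawn from a bivariate normal distribution with correlation
#' `rg_target`, so the correlation of the two genetic-value vectors converges
#' to `rg_target` as the causal set grows. Environmental noise is independent
#' between traits and scaled per trait to its heritability.
#'
#' @param G A `"geno_sim"` object.
#' @param h2_M,h2_N Heritabilities of the two traits.
#' @param rg_target Genetic correlation of the causal effects, in \[-1, 1\].
#' @param n_causal Number of shared causal markers.
#' @param seed Optional integer seed.
#' @return List with elements `M` and `N` (each a `"sim_trait"`) sharing
#'   `causal_indices`, and `rg_target`.
#' @export
simulate_correlated_pair <- function(G, h2_M, h2_N, rg_target,
                                     n_causal = 10, seed = NULL) {
  stopifnot(inherits(G, "geno_sim"))
  if (abs(rg_target) > 1) stop("'rg_target' must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(G$dosages)
  if (n_causal > m) stop("'n_causal' exceeds the number of markers")
  idx <- sort(sample.int(m, n_causal))
  a <- stats::rnorm(n_causal)
  b <- rg_target * a + sqrt(1 - rg_target^2) * stats::rnorm(n_causal)
  Z <- standardize_dosages(G, idx)
  gM <- drop(Z %*% a)
  gN <- drop(Z %*% b)
  n <- nrow(G$dosages)
  ids <- rownames(G$dosages)
  mk <- function(g, eff, h2) {
    y <- .add_noise(g, h2, n)
    names(y) <- ids
    structure(list(values = y, genetic_values = stats::setNames(g, ids),
                   causal_indices = idx, causal_effects = eff, true_h2 = h2),
              class = "sim_trait")
  }
  list(M = mk(gM, a, h2_M), N = mk(gN, b, h2_N), rg_target = rg_target)
}

#' Simulate blocks of mutually pleiotropic traits
#'
#' Builds `n_blocks` groups of `traits_per_block` traits. Traits within a
#' block share one causal marker set and have pairwise effect-size correlation
#' `rg_within` (each trait's effects are a mixture of a block-shared component
#' and an independent one); blocks use disjoint causal sets, so between-block
#' genetic correlations are approximately zero. This is the planted-structure
#' generator used to validate the clustering/meta-trait machinery.
#'
#' @param G A `"geno_sim"` object.
#' @param n_blocks Number of trait blocks.
#' @param traits_per_block Traits per block.
#' @param h2 Heritability of every trait.
#' @param rg_within Pairwise genetic correlation inside a block.
#' @param n_causal Causal markers per block.
#' @param seed Optional integer seed.
#' @return List with `values` (individuals x traits matrix of trait values),
#'   `blocks` (trait -> block integer vector) and `causal_sets`.
#' @export
simulate_trait_blocks <- function(G, n_blocks, traits_per_block, h2,
                                  rg_within = 0.9, n_causal = 10,
                                  seed = NULL) {
  stopifnot(inherits(G, "geno_sim"))
  if (rg_within < 0 || rg_within > 1) stop("'rg_within' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(G$dosages)
  if (n_blocks * n_causal > m)
    stop("not enough markers for disjoint causal sets")
  n <- nrow(G$dosages)
  all_idx <- sample.int(m, n_blocks * n_causal)
  Y <- matrix(NA_real_, n, n_blocks * traits_per_block,
              dimnames = list(rownames(G$dosages),
                              sprintf("b%02dt%02d", rep(seq_len(n_blocks),
                                                        each = traits_per_block),
                                      rep(seq_len(traits_per_block), n_blocks))))
  blocks <- rep(seq_len(n_blocks), each = traits_per_block)
  causal_sets <- vector("list", n_blocks)
  w <- sqrt(rg_within)
  col <- 0L
  for (b in seq_len(n_blocks)) {
    idx <- sort(all_idx[((b - 1) * n_causal + 1):(b * n_causal)])
    causal_sets[[b]] <- idx
    Z <- standardize_dosages(G, idx)
    shared <- stats::rnorm(n_causal)
    for (t in seq_len(traits_per_block)) {
      col <- col + 1L
      eff <- w * shared + sqrt(1 - rg_within) * stats::rnorm(n_causal)
      g <- drop(Z %*% eff)
      Y[, col] <- .add_noise(g, h2, n)
    }
  }
  names(blocks) <- colnames(Y)
  list(values = Y, blocks = blocks, causal_sets = causal_sets)
}

#' Simulate founder-haplotype probabilities
#'
#' Generates the 8-state (or `n_founders`-state) ancestry substrate of a
#' multiparental outbred cohort at unlinked markers: at each marker each
#' individual carries two founder alleles drawn uniformly, so the probability
#' vector has entries in \{0, 0.5, 1\} and sums to one.
#'
#' @param n_individuals Number of individuals.
#' @param n_markers Number of markers.
#' @param n_founders Number of founder haplotypes (default 8).
#' @param seed Optional integer seed.
#' @param n_chr,map_length Marker map layout, as in [simulate_genotypes()].
#' @return A `"founder_probs"` object: list with `probs` (individuals x
#'   markers x founders array), `map` and `founders`.
#' @export
simulate_founder_probs <- function(n_individuals, n_markers, n_founders = 8,
                                   seed = NULL, n_chr = 1, map_length = 100) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("ind%05d", seq_len(n_individuals))
  markers <- sprintf("m%05d", seq_len(n_markers))
  founders <- LETTERS[seq_len(n_founders)]
  P <- array(0, dim = c(n_individuals, n_markers, n_founders),
             dimnames = list(ids, markers, founders))
  a1 <- matrix(sample.int(n_founders, n_individuals * n_markers, TRUE),
               n_individuals, n_markers)
  a2 <- matrix(sample.int(n_founders, n_individuals * n_markers, TRUE),
               n_individuals, n_markers)
  for (f in seq_len(n_founders))
    P[, , f] <- 0.5 * ((a1 == f) + (a2 == f))
  chr <- sort(rep(seq_len(n_chr), length.out = n_markers))
  pos <- unlist(lapply(split(seq_len(n_markers), chr), function(ix)
    seq(0, map_length, length.out = length(ix) + 2L)[-c(1L, length(ix) + 2L)]),
    use.names = FALSE)
  map <- data.frame(marker = markers, chr = chr, pos = pos,
                    stringsAsFactors = FALSE)
  founder_probs(P, map)
}

#' Split a cohort into two disjoint random halves
#'
#' @param ids Character vector of individual IDs (or an integer cohort size,
#'   in which case indices are returned).
#' @param target_sizes Length-2 integer vector of subset sizes; defaults to an
#'   even split.
#' @param seed Optional integer seed; the same seed reproduces the split.
#' @return List with components `first` and `second`, disjoint subsets of
#'   `ids`.
#' @export
split_half <- function(ids, target_sizes = NULL, seed = NULL) {
  if (length(ids) == 1 && is.numeric(ids)) ids <- seq_len(ids)
  n <- length(ids)
  if (is.null(target_sizes)) target_sizes <- rep(floor(n / 2), 2)
  if (sum(target_sizes) > n)
    stop("target sizes exceed the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  pick <- sample(n, sum(target_sizes))
  list(first = ids[pick[seq_len(target_sizes[1])]],
       second = ids[pick[target_sizes[1] + seq_len(target_sizes[2])]])
}
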