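#' Founder-haplotype probability container
#'
#' Bundles an individuals x markers x founders probability array with its
#' marker map. Probabilities must be non-negative and sum to one (within
#' 1e-6) at every (individual, marker).
#'
#' @param probs Numeric array, individuals x markers x founders, with
#'   dimnames (individual IDs, marker names, founder labels).
#' @param map Data frame with columns `marker`, `chr`, `pos` (positions in
#'   Mb), one row per marker in array order.
#' @return An object of class `"founder_probs"`.
#' @export
founder_probs <- function(probs, map) {
  stopifnot(is.array(probs), length(dim(probs)) == 3)
  if (nrow(map) != dim(probs)[2])
    stop("map must have one row per marker")
  if (any(probs < -1e-9)) stop("founder probabilities must be non-negative")
  s <- apply(probs, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-6))
    stop("founder probabilities must sum to 1 at every (individual, marker)")
  structure(list(probs = probs, map = map,
                 founders = dimnames(probs)[[3]]),
            class = "founder_probs")
}

#' @export
print.founder_probs <- function(x, ...) {
  d <- dim(x$probs)
  cat("Founder probabilities:", d[1], "individuals x", d[2], "markers x",
      d[3], "founders\n")
  invisible(x)
}

#' Kinship from biallelic genotype dosages
#'
#' Computes the genomic relationship of every pair of individuals as the
#' cross-product of standardized genotypes averaged over markers, divided by
#' two so that entries approximate the probability of sampling the same
#' allele from two highly heterozygous individuals (matching
#' probability-based kinship conventions for multiparental populations).
#' Standardization uses the empirical allele frequency of the input cohort;
#' monomorphic markers are dropped with a warning.
#'
#' @param G A `"geno_sim"` object or a plain dosage matrix (individuals x
#'   markers, values in \{0,1,2\}) with rownames as individual IDs.
#' @return Symmetric kinship matrix with individual IDs as dimnames.
#' @examples
#' G <- simulate_genotypes(50, 100, seed = 4)
#' K <- kinship_from_genotypes(G)
#' isSymmetric(K)
#' @export
kinship_from_genotypes <- function(G) {
  X <- if (inherits(G, "geno_sim")) G$dosages else as.matrix(G)
  if (nrow(X) < 2) stop("need at least two individuals")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly))
    stop("all markers are monomorphic; kinship is undefined")
  if (any(!poly))
    warning(sum(!poly), " monomorphic marker(s) dropped from kinship")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(sweep(X, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / (2 * ncol(Z))
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

#' Kinship from founder-haplotype probabilities
#'
#' The kinship of individuals i and j is the average over markers of the
#' probability that a randomly sampled allele is from the same founder:
#' `K[i, j] = mean_m sum_f P[i, m, f] * P[j, m, f]`. The diagonal is computed
#' by the same rule.
#'
#' @param P A `"founder_probs"` object.
#' @return Symmetric kinship matrix with entries in \[0, 1\].
#' @export
kinship_from_founder_probs <- function(P) {
  stopifnot(inherits(P, "founder_probs"))
  d <- dim(P$probs)
  n <- d[1]; m <- d[2]; f <- d[3]
  # flatten to individuals x (marker, founder); the cross-product then sums
  # p_i p_j over founders and markers in one BLAS call
  flat <- matrix(P$probs, nrow = n)
  K <- tcrossprod(flat) / m
  dimnames(K) <- list(dimnames(P$probs)[[1]], dimnames(P$probs)[[1]])
  K
}

#' Interpolate founder probabilities onto a pseudomarker grid
#'
#' For every founder, probabilities are linearly interpolated in physical
#' position between the two flanking observed markers of the same
#' chromosome; pseudomarkers outside the observed range take the nearest
#' marker's probabilities (end clamping). Each interpolated vector is
#' re-normalized to sum to one, so output probabilities remain a valid
#' distribution.
#'
#' @param P A `"founder_probs"` object.
#' @param grid Data frame with columns `chr` and `pos` (and optionally
#'   `marker` names); chromosomes must be a subset of those in `P`.
#' @return A `"founder_probs"` object on the grid.
#' @export
interpolate_probs <- function(P, grid) {
  stopifnot(inherits(P, "founder_probs"))
  if (!all(c("chr", "pos") %in% names(grid)))
    stop("grid needs 'chr' and 'pos' columns")
  if (!all(unique(grid$chr) %in% unique(P$map$chr)))
    stop("grid chromosomes must be a subset of the input chromosomes")
  if (is.null(grid$marker))
    grid$marker <- sprintf("pm%05d", seq_len(nrow(grid)))
  d <- dim(P$probs)
  out <- array(NA_real_, dim = c(d[1], nrow(grid), d[3]),
               dimnames = list(dimnames(P$probs)[[1]], grid$marker,
                               dimnames(P$probs)[[3]]))
  for (ch in unique(grid$chr)) {
    src <- which(P$map$chr == ch)
    if (length(src) == 0) stop("empty chromosome in input: ", ch)
    tgt <- which(grid$chr == ch)
    x <- P$map$pos[src]
    ord <- order(x)
    src <- src[ord]; x <- x[ord]
    if (any(diff(grid$pos[tgt]) <= 0) && length(tgt) > 1)
      stop("grid positions must be strictly increasing within chromosome")
    xi <- pmin(pmax(grid$pos[tgt], x[1]), x[length(x)])  # end clamping
    if (length(x) == 1) {
      out[, tgt, ] <- P$probs[, rep(src, length(tgt)), ]
    } else {
      lo <- findInterval(xi, x, rightmost.closed = TRUE)
      hi <- pmin(lo + 1L, length(x))
      w <- ifelse(x[hi] > x[lo], (xi - x[lo]) / (x[hi] - x[lo]), 0)
      for (k in seq_along(tgt))
        out[, tgt[k], ] <- (1 - w[k]) * P$probs[, src[lo[k]], ] +
          w[k] * P$probs[, src[hi[k]], ]
    }
  }
  # renormalize to protect the simplex against accumulated rounding
  s <- apply(out, c(1, 2), sum)
  for (f in seq_len(d[3])) out[, , f] <- out[, , f] / s
  founder_probs(out, grid[, c("marker", "chr", "pos")])
}

#' Expand biallelic dosages into two-state allele probabilities
#'
#' Represents each biallelic marker as a two-"founder" probability pair
#' (dosage/2, 1 - dosage/2), so dosage matrices can be fed to the
#' founder-probability genome scan.
#'
#' @param G A `"geno_sim"` object or dosage matrix.
#' @param map Marker map (taken from `G` when it is a `"geno_sim"`).
#' @return A `"founder_probs"` object with two states.
#' @export
probs_from_dosages <- function(G, map = NULL) {
  X <- if (inherits(G, "geno_sim")) G$dosages else as.matrix(G)
  if (is.null(map)) {
    if (inherits(G, "geno_sim")) map <- G$map
    else map <- data.frame(marker = colnames(X),
                           chr = 1L, pos = seq_len(ncol(X)))
  }
  P <- array(NA_real_, dim = c(nrow(X), ncol(X), 2),
             dimnames = list(rownames(X), colnames(X), c("A", "B")))
  P[, , 1] <- X / 2
  P[, , 2] <- 1 - X / 2
  founder_probs(P, map)
}
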