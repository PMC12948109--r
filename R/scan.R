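#' Additive founder-haplotype genome scan
#'
#' Haley-Knott regression at every marker: the phenotype is regressed on
#' the founder-probability columns plus an intercept, and the LOD score is
#' `(n/2) * log10(RSS0 / RSS1)` against the intercept-only null. The
#' founder columns sum to one and are collinear with the intercept; the fit
#' uses a rank-revealing QR, and the LOD is invariant to the choice of
#' generalized inverse. Multiple phenotype columns (e.g. permuted copies)
#' are scanned in one pass.
#'
#' An optional kinship rotation is available for parity checks: with
#' `kinship = K` the phenotype and design are rotated by the
#' eigendecomposition of `2 K` and whitened using a null-model ML estimate
#' of the variance ratio, approximating a mixed-model scan. On unlinked
#' synthetic markers the correction is second-order; the default
#' fixed-effect scan is the package's reference method.
#'
#' @param Y Named numeric vector, or individuals x phenotypes matrix with
#'   rownames. Individuals with missing values are dropped (listwise for a
#'   matrix).
#' @param P A `"founder_probs"` object on the scan grid.
#' @param kinship Optional kinship matrix enabling the rotation variant.
#' @return Object of class `"scan_result"`: list with `lod` (markers x
#'   phenotypes matrix), `map`, `n_used`.
#' @export
genome_scan <- function(Y, P, kinship = NULL) {
  stopifnot(inherits(P, "founder_probs"))
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(names(Y), "pheno"))
  if (is.null(rownames(Y))) stop("'Y' must carry individual IDs")
  ids <- rownames(Y)[stats::complete.cases(Y)]
  ids <- intersect(ids, dimnames(P$probs)[[1]])
  n <- length(ids)
  nf <- dim(P$probs)[3]
  if (n < nf + 2) stop("too few phenotyped individuals for the scan")
  Ym <- Y[ids, , drop = FALSE]
  probs <- P$probs[ids, , drop = FALSE, ]
  ones <- rep(1, n)
  if (!is.null(kinship)) {
    ed <- eigen(2 * kinship[ids, ids], symmetric = TRUE)
    delta <- .null_delta(drop(crossprod(ed$vectors, Ym[, 1])),
                         drop(crossprod(ed$vectors, ones)), ed$values)
    wts <- 1 / sqrt(pmax(delta * ed$values, 0) + 1)
    Ym <- wts * crossprod(ed$vectors, Ym)
    probs_rot <- array(NA_real_, dim = dim(probs))
    for (f in seq_len(nf))
      probs_rot[, , f] <- wts * crossprod(ed$vectors, probs[, , f])
    probs <- probs_rot
    ones <- wts * drop(crossprod(ed$vectors, ones))
  }
  yss <- colSums(Ym^2)
  q0 <- qr.Q(qr(matrix(ones, ncol = 1)))
  rss0 <- yss - colSums(crossprod(q0, Ym)^2)
  m <- dim(probs)[2]
  lod <- matrix(NA_real_, m, ncol(Ym),
                dimnames = list(P$map$marker, colnames(Ym)))
  for (j in seq_len(m)) {
    X <- cbind(ones, probs[, j, ])
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    rss1 <- pmax(yss - colSums(crossprod(Q, Ym)^2), 1e-300)
    lod[j, ] <- (n / 2) * log10(rss0 / rss1)
  }
  lod[lod < 0] <- 0
  structure(list(lod = lod, map = P$map, n_used = n),
            class = "scan_result")
}

# ML estimate of the variance ratio delta = sigma2_g / sigma2_e on the
# rotated null model (intercept only); 1-D search on log10 delta.
.null_delta <- function(ystar, onestar, ev) {
  nll <- function(ld) {
    d <- 10^ld
    w <- 1 / (pmax(d * ev, 0) + 1)
    # GLS intercept
    mu <- sum(w * onestar * ystar) / sum(w * onestar^2)
    r <- ystar - mu * onestar
    s2 <- mean(w * r^2)
    length(ystar) * log(s2) - sum(log(w))
  }
  10^(stats::optimize(nll, c(-6, 6))$minimum)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Genome scan:", nrow(x$lod), "markers,", ncol(x$lod),
      "phenotype column(s),", x$n_used, "individuals; max LOD",
      sprintf("%.2f", max(x$lod)), "\n")
  invisible(x)
}

#' Permutation-based genome-wide significance threshold
#'
#' Unrestricted permutations: the phenotype vector is shuffled across
#' individuals, the whole-genome scan repeated, and the maximum LOD of
#' each permutation recorded. The empirical `1 - alpha` quantile of the
#' maximum-LOD distribution is the significance threshold (the 95th
#' percentile at the default `alpha = 0.05`).
#'
#' @param y Named phenotype vector.
#' @param P `"founder_probs"` scan grid.
#' @param n_perm Number of permutations (>= 20).
#' @param alpha Genome-wide error rate.
#' @param seed Optional integer seed.
#' @param keep_scans Keep the full permuted LOD profiles (needed for
#'   [permutation_fdr()]).
#' @param kinship Optional kinship for the rotation scan variant.
#' @return Object of class `"permutation_result"`: `max_lods`,
#'   `threshold`, `alpha`, `n_perm`, and `perm_lod` (markers x
#'   permutations) when `keep_scans = TRUE`.
#' @export
permutation_threshold <- function(y, P, n_perm = 1000, alpha = 0.05,
                                  seed = NULL, keep_scans = FALSE,
                                  kinship = NULL) {
  if (n_perm < 20) stop("need at least 20 permutations")
  if (!is.null(seed)) set.seed(seed)
  ok <- names(y)[is.finite(y)]
  yv <- y[ok]
  perms <- vapply(seq_len(n_perm), function(p) sample(yv), numeric(length(yv)))
  rownames(perms) <- ok
  colnames(perms) <- sprintf("perm%04d", seq_len(n_perm))
  sc <- genome_scan(perms, P, kinship = kinship)
  max_lods <- apply(sc$lod, 2, max)
  structure(list(max_lods = unname(max_lods),
                 threshold = unname(stats::quantile(max_lods, 1 - alpha)),
                 alpha = alpha, n_perm = n_perm,
                 perm_lod = if (keep_scans) sc$lod else NULL,
                 map = P$map),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation threshold (alpha = %g, %d permutations): LOD %.3f\n",
              x$alpha, x$n_perm, x$threshold))
  invisible(x)
}

# Peak LOD values of one profile: local maxima above `threshold`, where two
# maxima are distinct peaks only if the profile between them dips by at
# least `peakdrop` below the lower of the two.
.peak_lods <- function(lod, chr, threshold, peakdrop) {
  out <- numeric(0)
  for (ch in unique(chr)) {
    v <- lod[chr == ch]
    nn <- length(v)
    left <- c(-Inf, v[-nn])
    right <- c(v[-1], -Inf)
    cand <- which(v >= threshold & v >= left & v >= right)
    if (length(cand) == 0) next
    cand <- cand[order(v[cand], decreasing = TRUE)]
    acc <- integer(0)
    for (cidx in cand) {
      distinct <- TRUE
      for (aidx in acc) {
        rng <- if (cidx < aidx) cidx:aidx else aidx:cidx
        if (v[cidx] - min(v[rng]) < peakdrop) { distinct <- FALSE; break }
      }
      if (distinct) acc <- c(acc, cidx)
    }
    out <- c(out, v[acc])
  }
  out
}

#' Locate QTL peaks with 2-LOD support intervals
#'
#' Per chromosome, local maxima above `threshold` are candidate peaks; two
#' maxima count as distinct peaks only when the profile between them dips
#' by at least `peakdrop` below the lower of the two. Each peak's support
#' interval is the widest contiguous span around it where the LOD stays
#' within `drop` of the peak value, truncated at chromosome ends. Interval
#' geometry depends only on LOD differences, so it is invariant to uniform
#' LOD shifts.
#'
#' @param scan A `"scan_result"` (first phenotype column is used) or a
#'   numeric LOD vector.
#' @param map Marker map (`chr`, `pos`); taken from `scan` when absent.
#' @param threshold Minimum peak LOD (> 0).
#' @param drop LOD drop defining the support interval (default 2).
#' @param peakdrop Minimum dip separating distinct peaks (default 3).
#' @return Data frame: `chr`, `pos`, `lod`, `ci_lo`, `ci_hi`, `index`.
#' @export
find_peaks <- function(scan, map = NULL, threshold, drop = 2, peakdrop = 3) {
  if (inherits(scan, "scan_result")) {
    if (is.null(map)) map <- scan$map
    lod <- scan$lod[, 1]
  } else lod <- as.numeric(scan)
  if (threshold <= 0) stop("'threshold' must be positive")
  if (is.null(map))
    map <- data.frame(chr = 1L, pos = seq_along(lod))
  peaks <- list()
  for (ch in unique(map$chr)) {
    sel <- which(map$chr == ch)
    v <- lod[sel]
    nn <- length(v)
    left <- c(-Inf, v[-nn])
    right <- c(v[-1], -Inf)
    cand <- which(v >= threshold & v >= left & v >= right)
    if (length(cand) == 0) next
    cand <- cand[order(v[cand], decreasing = TRUE)]
    acc <- integer(0)
    for (cidx in cand) {
      distinct <- TRUE
      for (aidx in acc) {
        rng <- if (cidx < aidx) cidx:aidx else aidx:cidx
        if (v[cidx] - min(v[rng]) < peakdrop) { distinct <- FALSE; break }
      }
      if (distinct) acc <- c(acc, cidx)
    }
    for (pk in sort(acc)) {
      lo <- pk
      while (lo > 1 && v[lo - 1] >= v[pk] - drop) lo <- lo - 1
      hi <- pk
      while (hi < nn && v[hi + 1] >= v[pk] - drop) hi <- hi + 1
      peaks[[length(peaks) + 1]] <- data.frame(
        chr = ch, pos = map$pos[sel[pk]], lod = v[pk],
        ci_lo = map$pos[sel[lo]], ci_hi = map$pos[sel[hi]],
        index = sel[pk])
    }
  }
  if (length(peaks) == 0)
    return(data.frame(chr = integer(0), pos = numeric(0), lod = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0),
                      index = integer(0)))
  do.call(rbind, peaks)
}

#' Permutation-based false-discovery-rate curve
#'
#' At each LOD threshold `t` on the grid, peaks in each permuted scan are
#' counted as false discoveries `F_p` and peaks in the observed scan as
#' true discoveries `T`; `FDR(t) = mean_p [F_p / (F_p + T)]` (0/0 treated
#' as 0). The reported curve is made monotone non-increasing in `t` by a
#' running maximum over decreasing thresholds; raw values are retained.
#' Both the expected number of false discoveries `FDR * T` and of true
#' discoveries `(1 - FDR) * T` are reported with explicit labels.
#'
#' @param observed Observed `"scan_result"` or LOD vector.
#' @param perm A `"permutation_result"` with `keep_scans = TRUE`, or a
#'   markers x permutations LOD matrix.
#' @param map Marker map; taken from `observed`/`perm` when available.
#' @param lod_grid Thresholds at which to evaluate the curve.
#' @param drop,peakdrop Peak-finding parameters, held fixed across the
#'   observed and permuted scans.
#' @return Data frame: `lod`, `n_observed_peaks`, `mean_false_peaks`,
#'   `fdr_raw`, `fdr` (monotone), `expected_false`, `expected_true`.
#' @export
permutation_fdr <- function(observed, perm, map = NULL, lod_grid,
                            drop = 2, peakdrop = 3) {
  if (length(lod_grid) == 0) stop("empty LOD grid")
  if (inherits(observed, "scan_result")) {
    if (is.null(map)) map <- observed$map
    obs_lod <- observed$lod[, 1]
  } else obs_lod <- as.numeric(observed)
  if (inherits(perm, "permutation_result")) {
    if (is.null(perm$perm_lod))
      stop("permutation result lacks full scans; rerun with keep_scans = TRUE")
    if (is.null(map)) map <- perm$map
    perm_lod <- perm$perm_lod
  } else perm_lod <- as.matrix(perm)
  if (is.null(map)) map <- data.frame(chr = 1L, pos = seq_along(obs_lod))
  tmin <- min(lod_grid)
  obs_peaks <- .peak_lods(obs_lod, map$chr, tmin, peakdrop)
  perm_peaks <- lapply(seq_len(ncol(perm_lod)), function(p)
    .peak_lods(perm_lod[, p], map$chr, tmin, peakdrop))
  grid <- sort(lod_grid)
  res <- t(vapply(grid, function(t) {
    T_ <- sum(obs_peaks >= t)
    Fp <- vapply(perm_peaks, function(pk) sum(pk >= t), numeric(1))
    ratio <- ifelse(Fp + T_ == 0, 0, Fp / (Fp + T_))
    c(T_ = T_, meanF = mean(Fp), fdr = mean(ratio))
  }, numeric(3)))
  fdr_mono <- rev(cummax(rev(res[, "fdr"])))
  data.frame(lod = grid,
             n_observed_peaks = res[, "T_"],
             mean_false_peaks = res[, "meanF"],
             fdr_raw = res[, "fdr"],
             fdr = fdr_mono,
             expected_false = fdr_mono * res[, "T_"],
             expected_true = (1 - fdr_mono) * res[, "T_"])
}

#' Fraction of phenotypic variance explained by a QTL
#'
#' `1 - 10^(-(2/n) * LOD)`, with `n` the number of phenotyped animals and
#' `LOD` the score at the sentinel marker.
#'
#' @param lod LOD score(s).
#' @param n Number of observations.
#' @return Variance fraction(s) in \[0, 1).
#' @export
variance_explained <- function(lod, n) {
  if (any(n < 1) || any(lod < 0)) stop("need n >= 1 and lod >= 0")
  1 - 10^(-(2 / n) * lod)
}

#' Shrunken founder-allele effects at a locus
#'
#' Fits the founder effects at a single marker as random effects with one
#' variance component (ridge shrinkage): the phenotype and probability
#' columns are centered, and the shrinkage strength is chosen by
#' maximizing the single-locus marginal likelihood over the variance ratio
#' `lambda = sigma2_founder / sigma2_e` (1-D search on the log scale).
#' Centering the design makes the shrunken effects sum to zero exactly.
#' Standard errors come from the conditional posterior covariance. If the
#' likelihood search fails, fixed-effect (minimum-norm least-squares)
#' estimates are returned with a warning.
#'
#' @param y Named phenotype vector.
#' @param probs A `"founder_probs"` object, or an individuals x founders
#'   probability matrix at one marker.
#' @param marker Marker name or index (when `probs` is a container).
#' @param lambda Optional fixed variance ratio; `lambda -> 0` shrinks all
#'   effects to zero, large `lambda` approaches the fixed-effect fit.
#' @return Object of class `"founder_effects"`: `effects` (BLUPs, sum to
#'   ~0), `se`, `fixed` (unshrunken counterparts), `lambda`, `sigma2`.
#' @export
founder_effects <- function(y, probs, marker = NULL, lambda = NULL) {
  if (inherits(probs, "founder_probs")) {
    if (is.null(marker)) stop("'marker' required with a probability container")
    X <- probs$probs[, marker, ]
  } else X <- as.matrix(probs)
  ids <- intersect(names(y)[is.finite(y)], rownames(X))
  if (length(ids) < ncol(X) + 2) stop("too few phenotyped individuals")
  yv <- y[ids]
  X <- X[ids, , drop = FALSE]
  yc <- yv - mean(yv)
  Xc <- sweep(X, 2, colMeans(X))
  XtX <- crossprod(Xc)
  Xty <- drop(crossprod(Xc, yc))
  n <- length(yc)
  f <- ncol(X)
  nll <- function(ll) {
    lam <- 10^ll
    A <- XtX + diag(f) / lam
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(1e10)
    bb <- backsolve(cA, forwardsolve(t(cA), Xty))
    quad <- sum(yc^2) - sum(Xty * bb)
    # log det(I + lam X'X) = log det(A) + f log(lam)
    ld <- 2 * sum(log(diag(cA))) + f * log(lam)
    n * log(max(quad, 1e-300) / n) + ld
  }
  if (is.null(lambda)) {
    opt <- tryCatch(stats::optimize(nll, c(-8, 8)), error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) {
      warning("shrinkage optimizer failed; returning fixed-effect estimates")
      bf <- .minnorm_ls(Xc, yc)
      return(structure(list(effects = bf, se = rep(NA_real_, f),
                            fixed = bf, lambda = Inf, sigma2 = NA_real_),
                       class = "founder_effects"))
    }
    lambda <- 10^opt$minimum
  }
  A <- XtX + diag(f) / lambda
  Ainv <- solve(A)
  b <- drop(Ainv %*% Xty)
  quad <- sum(yc^2) - sum(Xty * b)
  sigma2 <- max(quad, 0) / n
  se <- sqrt(pmax(sigma2 * diag(Ainv), 0))
  bf <- .minnorm_ls(Xc, yc)
  names(b) <- names(se) <- names(bf) <- colnames(X)
  structure(list(effects = b, se = se, fixed = bf,
                 lambda = lambda, sigma2 = sigma2),
            class = "founder_effects")
}

# minimum-norm least squares via SVD (handles the sum-to-one collinearity)
.minnorm_ls <- function(Xc, yc) {
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-10
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos]))
}

#' @export
print.founder_effects <- function(x, ...) {
  cat("Founder effects (lambda =", format(x$lambda, digits = 3), "):\n")
  print(round(x$effects, 4))
  invisible(x)
}

#' Correlation of founder-effect vectors between two loci
#'
#' Pearson correlation of the shrunken founder-allele effects of two QTL,
#' with a two-sided t-test p-value on `founders - 2` degrees of freedom.
#' Used to ask whether two overlapping QTL act through the same founder
#' alleles.
#'
#' @param e1,e2 `"founder_effects"` objects or numeric effect vectors with
#'   matching founder names/ordering.
#' @return List with `r`, `p`, `df`.
#' @export
effect_correlation <- function(e1, e2) {
  v1 <- if (inherits(e1, "founder_effects")) e1$effects else e1
  v2 <- if (inherits(e2, "founder_effects")) e2$effects else e2
  if (length(v1) != length(v2)) stop("founder sets differ in length")
  if (!is.null(names(v1)) && !is.null(names(v2)) &&
      !identical(names(v1), names(v2)))
    stop("founder ordering differs between the two effect vectors")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero-variance effect vector")
  r <- stats::cor(v1, v2)
  df <- length(v1) - 2
  p <- if (abs(r) >= 1) 0
       else 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(r = r, p = p, df = df)
}
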