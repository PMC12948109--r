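#' Read and write kinship matrices as CSV
#'
#' Kinship matrices round-trip as CSV with individual IDs as a header row
#' and a leading ID column.
#'
#' @param K Kinship matrix with ID dimnames.
#' @param file Path to the CSV file.
#' @return `read_kinship` returns the kinship matrix; `write_kinship`
#'   returns `file` invisibly.
#' @export
write_kinship <- function(K, file) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (names(df)[1] != "id") stop("kinship CSV must have a leading 'id' column")
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df$id
  if (nrow(K) != ncol(K) || !identical(rownames(K), colnames(K)))
    stop("kinship CSV is not a square ID-labelled matrix")
  storage.mode(K) <- "double"
  if (any(!is.finite(K))) stop("kinship matrix contains non-finite values")
  if (max(abs(K - t(K))) > 1e-8) stop("kinship matrix is not symmetric")
  K
}

#' Read and write phenotype tables as CSV
#'
#' Phenotype tables are individuals x traits with a leading `id` column;
#' missing values are written as `NA`.
#'
#' @param Y Matrix or data frame of trait values with rownames (or an `id`
#'   column).
#' @param file Path to the CSV file.
#' @return `read_phenotypes` returns a numeric matrix with ID rownames.
#' @export
write_phenotypes <- function(Y, file) {
  Y <- as.data.frame(Y)
  if (is.null(Y$id)) Y <- cbind(id = rownames(Y), Y)
  utils::write.csv(Y, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (names(df)[1] != "id") stop("phenotype CSV must have a leading 'id' column")
  Y <- as.matrix(df[, -1, drop = FALSE])
  rownames(Y) <- df$id
  storage.mode(Y) <- "double"
  Y
}

#' Read and write genotype dosages with their marker map
#'
#' Dosages are written as an individuals x markers CSV (leading `id`
#' column) and the map as a separate CSV with `marker`, `chr`, `pos`
#' (positions in Mb, 1-based marker order).
#'
#' @param G A `"geno_sim"` object or dosage matrix.
#' @param file Dosage CSV path.
#' @param map_file Map CSV path (defaults to `file` with `_map` suffix).
#' @return `read_genotypes` returns a list with `dosages` and `map`.
#' @export
write_genotypes <- function(G, file, map_file = NULL) {
  X <- if (inherits(G, "geno_sim")) G$dosages else as.matrix(G)
  map <- if (inherits(G, "geno_sim")) G$map else NULL
  utils::write.csv(data.frame(id = rownames(X), X, check.names = FALSE),
                   file, row.names = FALSE)
  if (!is.null(map)) {
    if (is.null(map_file)) map_file <- sub("(\\.csv)?$", "_map.csv", file)
    utils::write.csv(map, map_file, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(file, map_file = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$id
  storage.mode(X) <- "double"
  if (is.null(map_file)) {
    cand <- sub("(\\.csv)?$", "_map.csv", file)
    map_file <- if (file.exists(cand)) cand else NULL
  }
  map <- if (!is.null(map_file)) utils::read.csv(map_file) else NULL
  list(dosages = X, map = map)
}

#' Read and write founder probabilities as a delimited-text container
#'
#' The container is a directory holding `map.csv` (columns `marker`,
#' `chr`, `pos`) and one `probs_<chr>.csv` per chromosome, each a wide
#' table with a leading `id` column and one `marker.founder` column per
#' (marker, founder) pair.
#'
#' @param P A `"founder_probs"` object.
#' @param dir Container directory (created if needed).
#' @return `read_founder_probs` returns a `"founder_probs"` object.
#' @export
write_founder_probs <- function(P, dir) {
  stopifnot(inherits(P, "founder_probs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(P$map, file.path(dir, "map.csv"), row.names = FALSE)
  founders <- dimnames(P$probs)[[3]]
  for (ch in unique(P$map$chr)) {
    sel <- which(P$map$chr == ch)
    flat <- do.call(cbind, lapply(sel, function(j) {
      m <- P$probs[, j, ]
      colnames(m) <- paste(P$map$marker[j], founders, sep = ".")
      m
    }))
    utils::write.csv(data.frame(id = dimnames(P$probs)[[1]], flat,
                                check.names = FALSE),
                     file.path(dir, sprintf("probs_%s.csv", ch)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_founder_probs
#' @export
read_founder_probs <- function(dir) {
  map <- utils::read.csv(file.path(dir, "map.csv"))
  chunks <- lapply(unique(map$chr), function(ch) {
    df <- utils::read.csv(file.path(dir, sprintf("probs_%s.csv", ch)),
                          check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$id
    m
  })
  flat <- do.call(cbind, chunks)
  founders <- unique(sub("^.*\\.", "", colnames(flat)))
  n <- nrow(flat)
  P <- array(NA_real_, dim = c(n, nrow(map), length(founders)),
             dimnames = list(rownames(flat), map$marker, founders))
  for (j in seq_len(nrow(map)))
    P[, j, ] <- flat[, paste(map$marker[j], founders, sep = "."),
                     drop = FALSE]
  founder_probs(P, map)
}
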