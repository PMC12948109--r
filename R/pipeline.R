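#' Default pipeline configuration
#'
#' Assembles a run configuration with the field defaults used throughout
#' the package: `h2_min = 0.10` (heritability filter), `outlier_sd = 5`
#' (outlier exclusion), `alpha = 0.05` and `n_perm = 1000` (permutation
#' significance), `lod_global = 6` (fixed phenome-wide LOD threshold),
#' `drop = 2` and `peakdrop = 3` (peak calling). When no input files are
#' supplied, the pipeline simulates a synthetic cohort whose parameters
#' live under `simulate`.
#'
#' @param out_dir Run directory.
#' @param seed Root seed; every stage derives its own seed from it.
#' @param ... Overrides for any top-level field or `simulate` subfield.
#' @return A nested list (class `"hegcor_config"`).
#' @export
default_config <- function(out_dir = "hegcor_run", seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = seed,
    pheno_file = NULL, covar_file = NULL, geno_file = NULL,
    kinship_file = NULL,
    diet_numeric = FALSE,
    h2_min = 0.10, outlier_sd = 5,
    alpha = 0.05, n_perm = 1000, lod_global = 6,
    drop = 2, peakdrop = 3,
    k_range = NULL,
    simulate = list(n_individuals = 300, n_markers = 400,
                    n_blocks = 3, traits_per_block = 4,
                    h2 = 0.5, rg_within = 0.9, n_causal = 10,
                    maf_pool = c(0.05, 0.1, 0.3, 0.4))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "simulate") cfg$simulate[names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  stopifnot(cfg$h2_min > 0, cfg$alpha > 0, cfg$outlier_sd > 0,
            cfg$drop > 0, cfg$peakdrop > 0, cfg$n_perm > 0)
  class(cfg) <- "hegcor_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param file Path to a YAML or JSON configuration file; fields override
#'   [default_config()] defaults.
#' @return A `"hegcor_config"` object.
#' @export
read_config <- function(file) {
  raw <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
         else jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(default_config, c(list(out_dir = raw$out_dir %||% "hegcor_run",
                                 seed = raw$seed %||% 1),
                            raw[setdiff(names(raw), c("out_dir", "seed"))]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.md5 <- function(files) {
  files <- files[file.exists(files)]
  as.list(tools::md5sum(files))
}

.stage_done <- function(manifest, name, inputs, outputs) {
  st <- manifest$stages[[name]]
  if (is.null(st)) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  cur_in <- .md5(inputs); cur_out <- .md5(outputs)
  identical(st$inputs, cur_in) && identical(st$outputs, cur_out)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> kinship -> prep -> h2 -> r_g atlas -> cluster /
#' meta-traits -> genome scans over a run directory, recording every
#' stage's parameters and input/output checksums in `manifest.json`.
#' Reruns with unchanged inputs resume from completed stages (matched by
#' checksum) and produce byte-identical outputs. A stage failure halts the
#' run with an error naming the stage.
#'
#' @param config A `"hegcor_config"` from [default_config()] or
#'   [read_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "hegcor_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "clusters"), showWarnings = FALSE)
  dir.create(file.path(out, "scans"), showWarnings = FALSE)
  man_file <- file.path(out, "manifest.json")
  manifest <- if (file.exists(man_file))
    jsonlite::read_json(man_file, simplifyVector = FALSE)
    else list(stages = list())
  record <- function(name, params, inputs, outputs) {
    manifest$stages[[name]] <<- list(params = params,
                                     inputs = .md5(inputs),
                                     outputs = .md5(outputs))
    jsonlite::write_json(manifest, man_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  stage <- function(name, inputs, outputs, params, fn) {
    if (.stage_done(manifest, name, inputs, outputs)) {
      message("stage '", name, "': up to date, skipped")
      return(invisible(NULL))
    }
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    record(name, params, inputs, outputs)
  }

  geno_file <- config$geno_file %||% file.path(out, "genotypes.csv")
  map_file <- sub("(\\.csv)?$", "_map.csv", geno_file)
  pheno_file <- config$pheno_file %||% file.path(out, "pheno_raw.csv")
  kin_file <- config$kinship_file %||% file.path(out, "kinship.csv")

  # -- simulate -------------------------------------------------------------
  if (is.null(config$pheno_file)) {
    sim <- config$simulate
    stage("simulate", character(0),
          c(geno_file, map_file, pheno_file),
          sim, function() {
      G <- simulate_genotypes(sim$n_individuals, sim$n_markers,
                              sim$maf_pool, seed = config$seed)
      blocks <- simulate_trait_blocks(G, sim$n_blocks, sim$traits_per_block,
                                      sim$h2, sim$rg_within, sim$n_causal,
                                      seed = config$seed + 1L)
      write_genotypes(G, geno_file)
      write_phenotypes(blocks$values, pheno_file)
      utils::write.csv(data.frame(trait = names(blocks$blocks),
                                  block = blocks$blocks),
                       file.path(out, "blocks.csv"), row.names = FALSE)
    })
  }

  # -- kinship --------------------------------------------------------------
  if (is.null(config$kinship_file)) {
    stage("kinship", geno_file, kin_file, list(), function() {
      G <- read_genotypes(geno_file)
      write_kinship(kinship_from_genotypes(G$dosages), kin_file)
    })
  } else {
    # provided kinship is validated here so that a corrupt file fails in
    # this stage, then copied into the run directory
    run_kin <- file.path(out, "kinship.csv")
    stage("kinship", kin_file, run_kin, list(source = kin_file), function() {
      K <- read_kinship(kin_file)
      write_kinship(K, run_kin)
    })
    kin_file <- run_kin
  }

  # -- phenotype preparation ------------------------------------------------
  adj_file <- file.path(out, "adjusted.csv")
  stage("prep", c(pheno_file, config$covar_file),
        adj_file, list(outlier_sd = config$outlier_sd), function() {
    Y <- read_phenotypes(pheno_file)
    covars <- if (!is.null(config$covar_file))
      utils::read.csv(config$covar_file) else NULL
    adj <- apply(Y, 2, function(y) {
      names(y) <- rownames(Y)
      adjust_and_normalize(remove_outliers(y, config$outlier_sd),
                           covars, config$diet_numeric)
    })
    write_phenotypes(adj, adj_file)
  })

  # -- heritability ---------------------------------------------------------
  h2_file <- file.path(out, "h2.csv")
  stage("h2", c(adj_file, kin_file), h2_file,
        list(h2_min = config$h2_min), function() {
    Y <- read_phenotypes(adj_file)
    K <- read_kinship(kin_file)
    ests <- lapply(colnames(Y), function(t) he_h2(Y[, t], K))
    names(ests) <- colnames(Y)
    filt <- filter_traits(ests, config$h2_min)
    tab <- data.frame(Trait = colnames(Y),
                      h2 = vapply(ests, `[[`, numeric(1), "h2"),
                      SE = vapply(ests, `[[`, numeric(1), "se_corrected"),
                      p = vapply(ests, `[[`, numeric(1), "p"),
                      n = vapply(ests, `[[`, numeric(1), "n_animals"),
                      keep = filt$keep, reason = filt$reason)
    utils::write.csv(tab, h2_file, row.names = FALSE)
    message("h2 stage: ", sum(!filt$keep), " trait(s) excluded (",
            paste(unique(filt$reason[filt$reason != ""]), collapse = "; "),
            ")")
  })

  # -- genetic-correlation atlas -------------------------------------------
  rg_file <- file.path(out, "rg.csv")
  rpg_file <- file.path(out, "rpg.csv")
  stage("rg", c(adj_file, kin_file, h2_file), c(rg_file, rpg_file),
        list(alpha = config$alpha), function() {
    Y <- read_phenotypes(adj_file)
    K <- read_kinship(kin_file)
    h2tab <- utils::read.csv(h2_file)
    kept <- h2tab$Trait[h2tab$keep]
    if (length(kept) < 3) stop("fewer than 3 traits pass the h2 filter")
    R <- rg_matrix(Y[, kept, drop = FALSE], K, config$alpha)
    ut <- which(upper.tri(R$rg), arr.ind = TRUE)
    long <- data.frame(Trait1 = kept[ut[, 1]], Trait2 = kept[ut[, 2]],
                       rg = R$rg[ut], SE = R$se[ut], rg_p = R$p[ut],
                       h2_1 = h2tab$h2[match(kept[ut[, 1]], h2tab$Trait)],
                       h2_2 = h2tab$h2[match(kept[ut[, 2]], h2tab$Trait)],
                       n_1 = h2tab$n[match(kept[ut[, 1]], h2tab$Trait)],
                       n_2 = h2tab$n[match(kept[ut[, 2]], h2tab$Trait)],
                       valid = R$valid[ut])
    utils::write.csv(long, rg_file, row.names = FALSE)
    rpg <- rpg_matrix(R)
    utils::write.csv(data.frame(trait = kept, rpg$rpg, check.names = FALSE),
                     rpg_file, row.names = FALSE)
    utils::write.csv(data.frame(trait = kept, rpg$n_obs, check.names = FALSE),
                     file.path(out, "rpg_nobs.csv"), row.names = FALSE)
  })

  # -- clustering and meta-traits ------------------------------------------
  asg_file <- file.path(out, "clusters", "assignments.csv")
  curve_file <- file.path(out, "clusters", "h2_ratio_curve.csv")
  meta_file <- file.path(out, "clusters", "meta_traits.csv")
  stage("cluster", c(adj_file, kin_file, rpg_file, h2_file),
        c(asg_file, curve_file, meta_file),
        list(k_range = config$k_range), function() {
    Y <- read_phenotypes(adj_file)
    K <- read_kinship(kin_file)
    rpg_df <- utils::read.csv(rpg_file, check.names = FALSE)
    traits <- rpg_df$trait
    rpg <- as.matrix(rpg_df[, -1]); dimnames(rpg) <- list(traits, traits)
    nobs_df <- utils::read.csv(file.path(out, "rpg_nobs.csv"),
                               check.names = FALSE)
    n_obs <- as.matrix(nobs_df[, -1]); dimnames(n_obs) <- dimnames(rpg)
    h2tab <- utils::read.csv(h2_file)
    h2v <- stats::setNames(h2tab$h2, h2tab$Trait)[traits]
    D <- rpg_to_distance(rpg, n_obs)
    if (any(!is.finite(D))) D[!is.finite(D)] <- max(D[is.finite(D)])
    dend <- ward_cluster(D)
    dend$labels <- traits
    sol <- sweep_k(dend, Y[, traits, drop = FALSE], K,
                   k_range = config$k_range, h2 = h2v, rpg = rpg)
    utils::write.csv(data.frame(Trait = names(sol$assignments),
                                Cluster = sol$assignments),
                     asg_file, row.names = FALSE)
    utils::write.csv(sol$curve, curve_file, row.names = FALSE)
    metas <- sapply(sort(unique(sol$assignments)), function(cl) {
      members <- names(sol$assignments)[sol$assignments == cl]
      build_meta_trait(Y[, members, drop = FALSE], h2v[members],
                       rpg[members, members, drop = FALSE])$values
    })
    colnames(metas) <- sprintf("meta_%03d", sort(unique(sol$assignments)))
    write_phenotypes(metas, meta_file)
  })

  # -- genome scans ---------------------------------------------------------
  peaks_file <- file.path(out, "scans", "peaks.csv")
  stage("scan", c(meta_file, geno_file),
        peaks_file, list(n_perm = config$n_perm, alpha = config$alpha,
                         drop = config$drop, peakdrop = config$peakdrop),
        function() {
    metas <- read_phenotypes(meta_file)
    G <- read_genotypes(geno_file)
    P <- probs_from_dosages(G$dosages, G$map)
    all_peaks <- list()
    for (mt in colnames(metas)) {
      y <- metas[, mt]
      names(y) <- rownames(metas)
      sc <- genome_scan(y, P)
      utils::write.csv(data.frame(marker = P$map$marker, chr = P$map$chr,
                                  pos = P$map$pos, lod = sc$lod[, 1]),
                       file.path(out, "scans", paste0("scan_", mt, ".csv")),
                       row.names = FALSE)
      perm <- permutation_threshold(y, P, config$n_perm, config$alpha,
                                    seed = config$seed + 2L)
      pk <- find_peaks(sc, threshold = perm$threshold,
                       drop = config$drop, peakdrop = config$peakdrop)
      if (nrow(pk) > 0) {
        pk <- cbind(Trait = mt, pk,
                    var_explained = variance_explained(pk$lod, sc$n_used),
                    threshold = perm$threshold)
        all_peaks[[mt]] <- pk
      }
    }
    peaks <- if (length(all_peaks)) do.call(rbind, all_peaks)
             else data.frame(Trait = character(0), chr = integer(0),
                             pos = numeric(0), lod = numeric(0),
                             ci_lo = numeric(0), ci_hi = numeric(0),
                             index = integer(0), var_explained = numeric(0),
                             threshold = numeric(0))
    utils::write.csv(peaks, peaks_file, row.names = FALSE)
  })

  invisible(manifest)
}
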