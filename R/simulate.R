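#' Default per-peak mean percentages for the 24-peak IgG glycan profile
#'
#' Means for the 22 peaks reported in published female twin cohorts, with
#' small conventional values for the two peaks (GP3, GP20) that derived-trait
#' tables typically omit; the vector is renormalized to sum to exactly 100.
#'
#' @return named numeric vector of length 24 summing to 100
#' @export
default_peak_means <- function() {
  m <- c(GP1 = 0.10, GP2 = 0.48, GP3 = 0.20, GP4 = 19.41, GP5 = 0.32,
         GP6 = 5.33, GP7 = 0.54, GP8 = 18.97, GP9 = 9.98, GP10 = 6.00,
         GP11 = 0.84, GP12 = 0.67, GP13 = 0.50, GP14 = 14.33, GP15 = 1.86,
         GP16 = 3.30, GP17 = 0.94, GP18 = 9.54, GP19 = 1.86, GP20 = 0.30,
         GP21 = 1.32, GP22 = 0.15, GP23 = 1.65, GP24 = 1.93)
  100 * m / sum(m)
}

#' Default trait variance-structure specifications
#'
#' Six standardized traits spanning the range of variance structures seen for
#' IgG glycan traits in twin data: strong and moderate additive genetic
#' control, a mixed ACE trait, strong and weak shared-environment (CE) traits,
#' and pure noise.
#'
#' @return data.frame with columns `name`, `a2`, `c2`, `e2`
#' @export
default_trait_specs <- function() {
  data.frame(
    name = c("trait_h80", "trait_h70", "trait_mixed",
             "trait_ce", "trait_ce_low", "trait_null"),
    a2 = c(0.80, 0.70, 0.36, 0.00, 0.00, 0.00),
    c2 = c(0.00, 0.00, 0.37, 0.66, 0.28, 0.00),
    e2 = c(0.20, 0.30, 0.27, 0.34, 0.72, 1.00),
    stringsAsFactors = FALSE
  )
}

#' Build and validate a cohort simulation configuration
#'
#' Defaults emulate the study conditions of a female adult twin cohort with
#' glycomics and methylation data: 220 MZ and 310 DZ pairs, pair-shared age
#' around 58 years, 24 UPLC glycan peaks expressed as percent of total area,
#' and standardized methylation probes carrying a family-shared intercept.
#'
#' @param n_mz,n_dz numbers of MZ and DZ twin pairs (each at least 1)
#' @param trait_specs data.frame with columns name, a2, c2, e2; each row must
#'   have nonnegative components summing to 1
#' @param covariate_model list with `age_mean`, `age_sd`, `bmi_mean`, `bmi_sd`,
#'   `n_batches`, and named numeric vectors `age_effects`, `batch_effects`
#'   (per-trait effect sizes on the standardized trait scale, default 0)
#' @param peak_model list with `means` (24 percentages summing to 100 within
#'   0.5) and `dispersion` (> 0; inverse Dirichlet concentration, larger means
#'   noisier compositions)
#' @param methyl_model list with `n_probes`, `family_var` (variance share of
#'   the family-shared probe intercept, in \\[0,1)), and `planted` (data.frame
#'   probe/trait/beta of effects wired into the trait generating equations)
#' @param seed master integer seed
#' @return validated config, class `sim_config`
#' @export
simulation_config <- function(n_mz = 220, n_dz = 310,
                              trait_specs = default_trait_specs(),
                              covariate_model = list(),
                              peak_model = list(),
                              methyl_model = list(),
                              seed = 1L) {
  covariate_model <- merge_defaults(
    list(age_mean = 58.71, age_sd = 9.37, bmi_mean = 26.6, bmi_sd = 4.8,
         n_batches = 4L, age_effects = numeric(0), batch_effects = numeric(0)),
    covariate_model)
  peak_model <- merge_defaults(
    list(means = default_peak_means(), dispersion = 0.01), peak_model)
  methyl_model <- merge_defaults(
    list(n_probes = 200L, family_var = 0.2,
         planted = data.frame(probe = character(0), trait = character(0),
                              beta = numeric(0))),
    methyl_model)
  cfg <- structure(
    list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
         trait_specs = trait_specs, covariate_model = covariate_model,
         peak_model = peak_model, methyl_model = methyl_model,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  ts <- cfg$trait_specs
  if (cfg$n_mz < 1L || cfg$n_dz < 1L)
    stop("invalid config: need at least one pair per zygosity", call. = FALSE)
  if (any(ts$a2 < 0 | ts$c2 < 0 | ts$e2 < 0))
    stop("invalid config: negative variance components", call. = FALSE)
  if (any(abs(ts$a2 + ts$c2 + ts$e2 - 1) > 1e-8))
    stop("invalid config: a2 + c2 + e2 must equal 1 for every trait",
         call. = FALSE)
  if (anyDuplicated(ts$name))
    stop("invalid config: duplicate trait names", call. = FALSE)
  pm <- cfg$peak_model
  if (length(pm$means) != 24L)
    stop("invalid config: peak_model$means must have 24 entries", call. = FALSE)
  if (abs(sum(pm$means) - 100) > 0.5)
    stop("invalid config: peak means must sum to 100 (within 0.5)",
         call. = FALSE)
  if (pm$dispersion <= 0)
    stop("invalid config: peak dispersion must be > 0", call. = FALSE)
  mm <- cfg$methyl_model
  if (nrow(mm$planted) > mm$n_probes)
    stop("invalid config: fewer probes than planted effects", call. = FALSE)
  if (mm$family_var < 0 || mm$family_var >= 1)
    stop("invalid config: family_var must lie in [0, 1)", call. = FALSE)
  unknown <- setdiff(mm$planted$trait, ts$name)
  if (length(unknown))
    stop("invalid config: planted effects reference unknown traits: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' Simulate one standardized twin trait
#'
#' Each pair is drawn from a zero-mean bivariate normal with unit variances
#' and cross-twin covariance a2 + c2 for MZ pairs and a2/2 + c2 for DZ pairs.
#' The additive part is shared exactly in MZ pairs and split into a shared and
#' a segregating half in DZ pairs, so the covariance algebra holds exactly.
#'
#' @param n_mz,n_dz pair counts
#' @param a2,c2 standardized additive and shared-environment variances;
#'   both nonnegative with a2 + c2 <= 1
#' @param seed optional seed applied before drawing
#' @return list with `mz` and `dz`, each an n x 2 matrix of co-twin values
#' @export
simulate_twin_trait <- function(n_mz, n_dz, a2, c2, seed = NULL) {
  if (a2 < 0 || c2 < 0 || a2 + c2 > 1 + 1e-12)
    stop("invalid config: need a2 >= 0, c2 >= 0 and a2 + c2 <= 1",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  e2 <- max(1 - a2 - c2, 0)
  # MZ: additive and shared-environment draws recycle across both columns
  mz <- matrix(rnorm(n_mz, 0, sqrt(a2)), n_mz, 2) +
    matrix(rnorm(n_mz, 0, sqrt(c2)), n_mz, 2) +
    matrix(rnorm(2 * n_mz, 0, sqrt(e2)), n_mz, 2)
  # DZ: additive part split into a pair-shared half and a segregating half
  a_sh <- rnorm(n_dz)
  a_seg <- matrix(rnorm(2 * n_dz), n_dz, 2)
  dz <- sqrt(a2) * (sqrt(0.5) * cbind(a_sh, a_sh) + sqrt(0.5) * a_seg) +
    matrix(rnorm(n_dz, 0, sqrt(c2)), n_dz, 2) +
    matrix(rnorm(2 * n_dz, 0, sqrt(e2)), n_dz, 2)
  dimnames(dz) <- NULL
  list(mz = mz, dz = dz)
}

#' Build the pair table for a cohort
#'
#' @param n_mz,n_dz pair counts
#' @return data.frame with pair_id, zygosity and the two member sample ids
#' @export
make_pair_table <- function(n_mz, n_dz) {
  n <- n_mz + n_dz
  pair_id <- sprintf("fam%04d", seq_len(n))
  data.frame(
    pair_id = pair_id,
    zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
    sample_1 = paste0(pair_id, "_1"),
    sample_2 = paste0(pair_id, "_2"),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-sample covariates for a twin cohort
#'
#' Co-twins share age and family id; the cohort is all female; BMI is drawn
#' per individual; batch, chip and chip position are assigned in blocks (12
#' samples per chip, matching common array plating) after a random shuffle.
#'
#' @param pair_table output of [make_pair_table()]
#' @param covariate_model list as in [simulation_config()]
#' @param seed optional seed
#' @return data.frame keyed by sample_id
#' @export
simulate_covariates <- function(pair_table, covariate_model = list(),
                                seed = NULL) {
  if (nrow(pair_table) == 0L) stop("pair_table is empty", call. = FALSE)
  cm <- merge_defaults(list(age_mean = 58.71, age_sd = 9.37, bmi_mean = 26.6,
                        bmi_sd = 4.8, n_batches = 4L), covariate_model)
  if (!is.null(seed)) set.seed(seed)
  npair <- nrow(pair_table)
  age_pair <- rnorm(npair, cm$age_mean, cm$age_sd)
  samples <- data.frame(
    sample_id = c(rbind(pair_table$sample_1, pair_table$sample_2)),
    pair_id = rep(pair_table$pair_id, each = 2),
    zygosity = rep(pair_table$zygosity, each = 2),
    age = rep(age_pair, each = 2),
    sex = "F",
    stringsAsFactors = FALSE
  )
  n <- nrow(samples)
  samples$bmi <- rnorm(n, cm$bmi_mean, cm$bmi_sd)
  ord <- sample.int(n)
  batch <- integer(n); chip <- integer(n); pos <- integer(n)
  batch[ord] <- rep_len(seq_len(cm$n_batches), n)
  chip[ord] <- (seq_len(n) - 1L) %/% 12L + 1L
  pos[ord] <- (seq_len(n) - 1L) %% 12L + 1L
  samples$batch <- batch
  samples$chip <- chip
  samples$chip_pos <- pos
  samples
}

#' Simulate glycan peak profiles on the 24-peak simplex
#'
#' Rows are Dirichlet draws scaled to sum to 100, with expectation equal to
#' the configured mean percentages. The dispersion parameter is the inverse of
#' the Dirichlet concentration: larger values give noisier compositions.
#'
#' @param n_samples number of rows
#' @param peak_model list with `means` and `dispersion`
#' @param seed optional seed
#' @return n_samples x 24 matrix, rows summing to 100
#' @export
simulate_peak_profiles <- function(n_samples, peak_model = list(),
                                   seed = NULL) {
  pm <- merge_defaults(list(means = default_peak_means(), dispersion = 0.01),
                   peak_model)
  if (length(pm$means) != 24L || abs(sum(pm$means) - 100) > 0.5)
    stop("invalid config: peak means must be 24 values summing to 100",
         call. = FALSE)
  if (pm$dispersion <= 0)
    stop("invalid config: dispersion must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  alpha <- (pm$means / sum(pm$means)) / pm$dispersion
  g <- matrix(rgamma(n_samples * 24L, shape = rep(alpha, each = n_samples)),
              n_samples, 24L)
  out <- 100 * g / rowSums(g)
  colnames(out) <- if (is.null(names(pm$means))) paste0("GP", 1:24)
                   else names(pm$means)
  out
}

#' Simulate a standardized methylation matrix with planted trait effects
#'
#' Probes are simulated directly on the standardized scale: each probe is a
#' family-shared intercept (variance `family_var`) plus individual noise, so
#' columns have population mean 0 and variance 1. For every planted
#' (probe, trait, beta) the trait generating equation gains beta times the
#' probe values, which is what a downstream association scan should recover.
#'
#' @param pair_table output of [make_pair_table()]
#' @param trait_matrix samples x traits matrix (rownames = sample ids)
#' @param methyl_model list as in [simulation_config()]
#' @param seed optional seed
#' @return list with `methyl` (samples x probes), `annotation` (probe, chr,
#'   position, gene) and `traits` (trait matrix with planted effects added)
#' @export
simulate_methylation <- function(pair_table, trait_matrix,
                                 methyl_model = list(), seed = NULL) {
  mm <- merge_defaults(list(n_probes = 200L, family_var = 0.2,
                        planted = data.frame(probe = character(0),
                                             trait = character(0),
                                             beta = numeric(0))),
                   methyl_model)
  unknown <- setdiff(mm$planted$trait, colnames(trait_matrix))
  if (length(unknown))
    stop("planted effects reference unknown traits: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  npair <- nrow(pair_table)
  n <- 2L * npair
  p <- as.integer(mm$n_probes)
  u <- mm$family_var
  fam <- matrix(rnorm(npair * p), npair, p)[rep(seq_len(npair), each = 2), ,
                                            drop = FALSE]
  methyl <- sqrt(u) * fam + sqrt(1 - u) * matrix(rnorm(n * p), n, p)
  probe_ids <- if (nrow(mm$planted) && all(grepl("^cg", mm$planted$probe))) {
    ids <- sprintf("cg%07d", seq_len(p))
    ids[seq_len(nrow(mm$planted))] <- mm$planted$probe
    ids
  } else sprintf("cg%07d", seq_len(p))
  # planted probes occupy the first columns when custom ids are supplied
  colnames(methyl) <- probe_ids
  rownames(methyl) <- c(rbind(pair_table$sample_1, pair_table$sample_2))
  annotation <- data.frame(
    probe = probe_ids,
    chr = rep_len(1:22, p),
    position = 1e6L + 137L * seq_len(p),
    gene = sprintf("GENE%04d", seq_len(p)),
    stringsAsFactors = FALSE
  )
  traits <- trait_matrix
  if (nrow(mm$planted)) {
    for (i in seq_len(nrow(mm$planted))) {
      pl <- mm$planted[i, ]
      if (!pl$probe %in% colnames(methyl))
        stop("planted probe not present in matrix: ", pl$probe, call. = FALSE)
      traits[, pl$trait] <- traits[, pl$trait] +
        pl$beta * methyl[rownames(traits), pl$probe]
    }
  }
  list(methyl = methyl, annotation = annotation, traits = traits)
}

#' Simulate a complete twin cohort with known ground truth
#'
#' Stages (pairs, covariates, base traits, methylation, peaks) each draw from
#' a deterministic substream of the master seed, so the cohort is reproducible
#' bit-for-bit and extending one stage does not disturb the others. Trait
#' generating model per sample: standardized A+C+E value, plus planted
#' methylation effects, plus age and batch fixed effects.
#'
#' @param config a [simulation_config()] object
#' @return list of class `twin_cohort`: `pairs`, `covariates`, `traits`
#'   (samples x traits), `peaks` (samples x 24), `methyl`,
#'   `methyl_annotation`, and `truth` (the config)
#' @export
simulate_cohort <- function(config = simulation_config()) {
  validate_simulation_config(config)
  pairs <- make_pair_table(config$n_mz, config$n_dz)
  covars <- simulate_covariates(pairs, config$covariate_model,
                                seed = substream_seed(config$seed, "covariates"))
  set.seed(substream_seed(config$seed, "traits"))
  ts <- config$trait_specs
  traits <- matrix(NA_real_, 2L * nrow(pairs), nrow(ts),
                   dimnames = list(c(rbind(pairs$sample_1, pairs$sample_2)),
                                   ts$name))
  is_mz <- pairs$zygosity == "MZ"
  for (j in seq_len(nrow(ts))) {
    tw <- simulate_twin_trait(sum(is_mz), sum(!is_mz), ts$a2[j], ts$c2[j])
    vals <- matrix(NA_real_, nrow(pairs), 2)
    vals[is_mz, ] <- tw$mz
    vals[!is_mz, ] <- tw$dz
    traits[, j] <- c(t(vals))
  }
  meth <- simulate_methylation(pairs, traits, config$methyl_model,
                               seed = substream_seed(config$seed, "methylation"))
  traits <- meth$traits
  # covariate fixed effects, added after the standardized genetic base
  cm <- config$covariate_model
  age_c <- covars$age - mean(covars$age)
  batch_dev <- covars$batch - mean(covars$batch)
  for (nm in names(cm$age_effects)) {
    traits[, nm] <- traits[, nm] + cm$age_effects[[nm]] * age_c
  }
  for (nm in names(cm$batch_effects)) {
    traits[, nm] <- traits[, nm] + cm$batch_effects[[nm]] * batch_dev
  }
  peaks <- simulate_peak_profiles(2L * nrow(pairs), config$peak_model,
                                  seed = substream_seed(config$seed, "peaks"))
  rownames(peaks) <- rownames(traits)
  structure(
    list(pairs = pairs, covariates = covars, traits = traits, peaks = peaks,
         methyl = meth$methyl, methyl_annotation = meth$annotation,
         truth = config),
    class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("Synthetic twin cohort:",
      sum(x$pairs$zygosity == "MZ"), "MZ +",
      sum(x$pairs$zygosity == "DZ"), "DZ pairs\n")
  cat("  traits:", ncol(x$traits),
      "| peaks:", ncol(x$peaks),
      "| probes:", ncol(x$methyl),
      "| planted effects:", nrow(x$truth$methyl_model$planted), "\n")
  invisible(x)
}

#' Write a simulated cohort to delimited text files
#'
#' Writes pairs.tsv, covariates.tsv, traits.tsv, peaks.tsv, methylation.tsv,
#' methyl_annotation.tsv and truth.yaml into `dir`.
#'
#' @param cohort a `twin_cohort`
#' @param dir output directory (created if missing)
#' @return invisibly, the vector of written paths
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    pairs = file.path(dir, "pairs.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    traits = file.path(dir, "traits.tsv"),
    peaks = file.path(dir, "peaks.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    methyl_annotation = file.path(dir, "methyl_annotation.tsv"),
    truth = file.path(dir, "truth.yaml")
  )
  write_tsv(cohort$pairs, paths["pairs"])
  write_tsv(cohort$covariates, paths["covariates"])
  write_tsv(matrix_to_table(cohort$traits), paths["traits"])
  write_tsv(matrix_to_table(cohort$peaks), paths["peaks"])
  write_tsv(matrix_to_table(cohort$methyl), paths["methylation"])
  write_tsv(cohort$methyl_annotation, paths["methyl_annotation"])
  truth <- unclass(cohort$truth)
  truth$trait_specs <- as.list(as.data.frame(truth$trait_specs))
  truth$methyl_model$planted <- as.list(truth$methyl_model$planted)
  truth$peak_model$means <- as.list(truth$peak_model$means)
  yaml::write_yaml(truth, paths["truth"])
  invisible(paths)
}
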