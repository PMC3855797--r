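#' Residualize a trait on age and batch and standardize
#'
#' Least-squares residuals of the trait on age and batch indicators, rescaled
#' to mean 0 and unit variance — the covariate pre-adjustment applied before
#' the twin likelihood so that it stays two-dimensional per pair.
#'
#' @param values named numeric vector (names = sample ids) or plain vector
#' @param covariates data.frame with sample_id, age, batch for (at least) the
#'   named samples
#' @return named numeric vector of adjusted standardized values
#' @export
residualize_trait <- function(values, covariates) {
  if (is.null(names(values)) && nrow(covariates) == length(values))
    names(values) <- covariates$sample_id
  idx <- match(names(values), covariates$sample_id)
  if (anyNA(idx))
    stop("covariates missing for samples: ",
         paste(names(values)[is.na(idx)][1:min(5, sum(is.na(idx)))],
               collapse = ", "), call. = FALSE)
  cv <- covariates[idx, ]
  keep <- is.finite(values) & is.finite(cv$age) & !is.na(cv$batch)
  y <- values[keep]
  if (length(unique(y)) < 2L || sd(y) == 0)
    stop("degenerate trait: constant values", call. = FALSE)
  df <- data.frame(y = y, age = cv$age[keep], batch = factor(cv$batch[keep]))
  fit <- if (nlevels(df$batch) >= 2L) lm(y ~ age + batch, data = df)
         else lm(y ~ age, data = df)
  r <- resid(fit)
  r <- (r - mean(r)) / sd(r)
  out <- setNames(rep(NA_real_, length(values)), names(values))
  out[keep] <- r
  out
}

#' Assemble per-pair trait records from a sample-level vector
#'
#' @param values named numeric vector of (adjusted) trait values
#' @param pair_table data.frame with pair_id, zygosity, sample_1, sample_2
#' @return data.frame with pair_id, zygosity, value_1, value_2, complete
#' @export
make_twin_pairs <- function(values, pair_table) {
  out <- data.frame(
    pair_id = pair_table$pair_id,
    zygosity = pair_table$zygosity,
    value_1 = unname(values[pair_table$sample_1]),
    value_2 = unname(values[pair_table$sample_2]),
    stringsAsFactors = FALSE)
  out$complete <- is.finite(out$value_1) & is.finite(out$value_2)
  out
}

#' Classify traits by heritability
#'
#' Low heritability means the best-fitting model carries no additive
#' component (CE or E) or its additive share does not exceed the threshold
#' (inclusive: a2 equal to the threshold counts as low).
#'
#' @param decompositions data.frame with columns trait, model, a2
#' @param threshold heritability cut point (default 0.35)
#' @return data.frame with trait, class ("low"/"high"), basis
#' @export
classify_heritability <- function(decompositions, threshold = 0.35) {
  no_a <- decompositions$model %in% c("CE", "E")
  low <- no_a | decompositions$a2 <= threshold
  data.frame(
    trait = decompositions$trait,
    class = ifelse(low, "low", "high"),
    basis = ifelse(no_a, "no additive component",
                   sprintf("h2=%.2f", decompositions$a2)),
    stringsAsFactors = FALSE)
}

#' Heritability screen across a trait matrix
#'
#' For each trait: adjust for age and batch (when covariates are supplied),
#' standardize, fit the four twin submodels, select the best, and report a
#' table with one row per trait — unadjusted per-zygosity means and SDs,
#' double-entry ICCs with intervals, the selected model, the standardized
#' A/C/E shares with profile intervals, and the heritability class.
#'
#' @param trait_matrix samples x traits matrix (rownames = sample ids)
#' @param pair_table data.frame with pair_id, zygosity, sample_1, sample_2
#' @param covariates optional data.frame with sample_id, age, batch
#' @param alpha drop-test level for model selection
#' @param threshold heritability classification cut point
#' @param ci compute profile intervals (slower)
#' @param level confidence level
#' @param mixture boundary-mixture LRT reference (see [twin_ace()])
#' @return data.frame, one row per trait
#' @export
heritability_screen <- function(trait_matrix, pair_table, covariates = NULL,
                                alpha = 0.05, threshold = 0.35, ci = TRUE,
                                level = 0.95, mixture = FALSE) {
  if (is.data.frame(trait_matrix) && "sample_id" %in% names(trait_matrix))
    trait_matrix <- table_to_matrix(trait_matrix)
  rows <- list()
  for (tr in colnames(trait_matrix)) {
    vals <- setNames(trait_matrix[, tr], rownames(trait_matrix))
    adj <- tryCatch(
      if (is.null(covariates)) {
        if (sd(vals, na.rm = TRUE) == 0)
          stop("degenerate trait: constant values", call. = FALSE)
        (vals - mean(vals, na.rm = TRUE)) / sd(vals, na.rm = TRUE)
      } else residualize_trait(vals, covariates),
      error = function(e) e)
    if (inherits(adj, "error")) {
      message("skipping trait '", tr, "': ", conditionMessage(adj))
      next
    }
    pairs <- make_twin_pairs(adj, pair_table)
    fit <- twin_ace(pairs, alpha = alpha, ci = ci, level = level,
                    mixture = mixture)
    raw_pairs <- make_twin_pairs(vals, pair_table)
    mz_raw <- unlist(raw_pairs[raw_pairs$zygosity == "MZ",
                               c("value_1", "value_2")])
    dz_raw <- unlist(raw_pairs[raw_pairs$zygosity == "DZ",
                               c("value_1", "value_2")])
    ci_or_na <- function(cmp, j)
      if (is.null(fit$ci) || any(is.na(fit$ci[[cmp]]))) NA_real_
      else fit$ci[[cmp]][j]
    rows[[tr]] <- data.frame(
      trait = tr, n_mz = fit$n_mz, n_dz = fit$n_dz,
      mz_mean = mean(mz_raw, na.rm = TRUE), mz_sd = sd(mz_raw, na.rm = TRUE),
      icc_mz = fit$icc$mz$estimate, icc_mz_lo = fit$icc$mz$lower,
      icc_mz_hi = fit$icc$mz$upper,
      dz_mean = mean(dz_raw, na.rm = TRUE), dz_sd = sd(dz_raw, na.rm = TRUE),
      icc_dz = fit$icc$dz$estimate, icc_dz_lo = fit$icc$dz$lower,
      icc_dz_hi = fit$icc$dz$upper,
      model = fit$model,
      a2 = unname(fit$shares["a2"]), a2_lo = ci_or_na("a2", 1),
      a2_hi = ci_or_na("a2", 2),
      c2 = unname(fit$shares["c2"]), c2_lo = ci_or_na("c2", 1),
      c2_hi = ci_or_na("c2", 2),
      e2 = unname(fit$shares["e2"]), e2_lo = ci_or_na("e2", 1),
      e2_hi = ci_or_na("e2", 2),
      h2 = if (fit$model %in% c("CE", "E")) NA_real_
           else unname(fit$shares["a2"]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cls <- classify_heritability(out, threshold)
  out$class <- cls$class[match(out$trait, cls$trait)]
  out
}

#' Simulation-based power to detect an additive genetic component
#'
#' For each replicate a cohort of the given size and true (a2, c2) is
#' simulated and the additive component is tested by the likelihood-ratio
#' test that drops A from the full ACE model (ACE vs CE, one degree of
#' freedom) — the same drop the sequential model-selection procedure uses.
#' Power is the rejection fraction at `alpha`, reported with its binomial
#' Monte-Carlo standard error. This test is size-correct for any true
#' shared-environment level and its power is monotone in the cohort size;
#' at the a2 = 0 boundary the plain chi-square reference is conservative
#' (empirical size at or below `alpha`), and the optional 50:50 mixture
#' reference restores the nominal level.
#'
#' @param n_mz,n_dz pair counts
#' @param a2,c2 true standardized components
#' @param alpha test level
#' @param n_reps number of replicates (at least 100)
#' @param seed optional seed
#' @param mixture use the 50:50 boundary-mixture reference
#' @return list with `power`, `se`, `n_reps`, `rejections`
#' @export
twin_power <- function(n_mz, n_dz, a2, c2, alpha = 0.05, n_reps = 500,
                       seed = NULL, mixture = FALSE) {
  if (n_reps < 100) stop("need at least 100 replicates", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rej <- 0L
  for (r in seq_len(n_reps)) {
    tw <- simulate_twin_trait(n_mz, n_dz, a2, c2)
    smz <- twin_suff(tw$mz)
    sdz <- twin_suff(tw$dz)
    lr <- 2 * (fit_model_suff(smz, sdz, "ACE")$loglik -
                 fit_model_suff(smz, sdz, "CE")$loglik)
    p <- pchisq(max(lr, 0), 1, lower.tail = FALSE)
    if (mixture) p <- p / 2
    if (p < alpha) rej <- rej + 1L
  }
  power <- rej / n_reps
  list(power = power, se = sqrt(power * (1 - power) / n_reps),
       n_reps = n_reps, rejections = rej)
}
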