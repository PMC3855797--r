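#' Standardize methylation probes to mean zero, variance one
#'
#' Column-wise (x - mean) / SD using the sample SD. Constant probes are
#' dropped with a message; an error is raised if nothing remains.
#'
#' @param m samples x probes matrix
#' @return standardized matrix (possibly fewer columns)
#' @export
standardize_probes <- function(m) {
  if (is.data.frame(m) && "sample_id" %in% names(m)) m <- table_to_matrix(m)
  sds <- apply(m, 2, sd)
  const <- !is.finite(sds) | sds == 0
  if (all(const)) stop("all probes are constant", call. = FALSE)
  if (any(const))
    message("dropping ", sum(const), " constant probe(s): ",
            paste(utils::head(colnames(m)[const], 5), collapse = ", "))
  m <- m[, !const, drop = FALSE]
  scale(m)[, , drop = FALSE]
}

# design matrix for the fixed-effect covariates; aliased columns dropped with
# a warning, categorical chip variables expanded to indicators
build_covar_matrix <- function(covariates, samples) {
  if (is.null(covariates)) return(NULL)
  idx <- match(samples, covariates$sample_id)
  if (anyNA(idx))
    stop("covariates missing for samples: ",
         paste(samples[is.na(idx)][1:min(5, sum(is.na(idx)))],
               collapse = ", "), call. = FALSE)
  cv <- covariates[idx, , drop = FALSE]
  cols <- intersect(c("age", "sex", "bmi", "batch", "chip", "chip_pos",
                      "zygosity"),
                    names(cv))
  cols <- setdiff(cols, "zygosity")  # sensitivity covariate, off by default
  if (!length(cols)) return(NULL)
  df <- cv[, cols, drop = FALSE]
  for (categorical in intersect(c("sex", "batch", "chip", "chip_pos"),
                                names(df)))
    df[[categorical]] <- factor(df[[categorical]])
  # constant columns (e.g. sex in an all-female cohort) carry no information
  keep_col <- vapply(df, function(x) length(unique(x)) > 1L, logical(1))
  df <- df[, keep_col, drop = FALSE]
  if (!ncol(df)) return(NULL)
  X <- model.matrix(~ ., data = df)[, -1, drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    keep <- qrX$pivot[seq_len(qrX$rank)] - 1L
    keep <- keep[keep > 0]
    warning("dropping ", ncol(X) - length(keep),
            " aliased covariate column(s)", call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  X
}

#' Family random-intercept association between a trait and one probe
#'
#' Linear mixed model y = beta * m + covariates + u_family + e, fitted by
#' REML with a single family variance component; the Wald p-value for beta
#' uses the standard normal reference by default (a t reference with
#' residual degrees of freedom is available via `use_t`).
#'
#' @param y numeric trait values
#' @param m numeric probe values (same length/order)
#' @param covariates optional fixed-effect design matrix (or NULL)
#' @param family_ids grouping factor linking co-twins
#' @param use_t use a t reference with n - p - 1 df instead of the normal
#' @return list with `beta`, `se`, `p`, `family_var`, `resid_var`
#' @export
fit_random_intercept <- function(y, m, covariates = NULL, family_ids,
                                 use_t = FALSE) {
  df <- data.frame(y = y, m = m, fam = factor(family_ids))
  form <- "y ~ m"
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    colnames(covariates) <- paste0("X", seq_len(ncol(covariates)))
    df <- cbind(df, covariates)
    form <- paste(form, "+", paste(colnames(covariates), collapse = " + "))
  }
  form <- paste(form, "+ (1 | fam)")
  fit <- lme4::lmer(as.formula(form), data = df, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  beta <- lme4::fixef(fit)[["m"]]
  se <- sqrt(as.matrix(vcov(fit))["m", "m"])
  stat <- beta / se
  p <- if (use_t) {
    dfree <- nrow(df) - length(lme4::fixef(fit)) - 1
    2 * pt(-abs(stat), dfree)
  } else 2 * pnorm(-abs(stat))
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(beta = beta, se = se, p = p,
       family_var = vc$vcov[vc$grp == "fam"],
       resid_var = vc$vcov[vc$grp == "Residual"])
}

#' Array-wide Bonferroni threshold
#'
#' @param alpha family-wise level
#' @param n_probes number of probes tested
#' @return list with the exact `threshold` (alpha / n_probes) and its
#'   one-significant-figure `reported` form used in summaries
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_probes) {
  if (n_probes < 1) stop("need at least one probe", call. = FALSE)
  thr <- alpha / n_probes
  list(threshold = thr, reported = signif(thr, 1))
}

#' Epigenome-wide association scan of glycan traits
#'
#' Fits the family random-intercept regression for every (probe, trait)
#' combination, returning one record per pair sorted by p-value, with probe
#' annotation merged in for reporting.
#'
#' @param trait_matrix samples x traits matrix (rownames = sample ids)
#' @param traits character vector of trait columns to scan
#' @param methyl standardized samples x probes matrix
#' @param covariates optional covariate data.frame (sample_id key) used as
#'   fixed effects; its `pair_id` column supplies the family grouping
#' @param annotation probe annotation (probe, chr, position, gene)
#' @param threshold significance threshold on p (e.g. the Bonferroni cutoff)
#' @param family_ids optional explicit family grouping (overrides covariates)
#' @return data.frame with probe, chr, position, gene, trait, beta, se, p,
#'   significant
#' @export
run_ewas <- function(trait_matrix, traits, methyl, covariates = NULL,
                     annotation = NULL, threshold = 0.05,
                     family_ids = NULL) {
  if (is.data.frame(trait_matrix) && "sample_id" %in% names(trait_matrix))
    trait_matrix <- table_to_matrix(trait_matrix)
  if (is.data.frame(methyl) && "sample_id" %in% names(methyl))
    methyl <- table_to_matrix(methyl)
  if (!length(traits)) stop("empty trait subset", call. = FALSE)
  miss <- setdiff(traits, colnames(trait_matrix))
  if (length(miss))
    stop("traits not present: ", paste(miss, collapse = ", "), call. = FALSE)
  samples <- rownames(trait_matrix)
  bad <- setdiff(samples, rownames(methyl))
  if (length(bad))
    stop("sample ids missing from methylation matrix: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  methyl <- methyl[samples, , drop = FALSE]
  if (is.null(family_ids)) {
    if (is.null(covariates) || !"pair_id" %in% names(covariates))
      stop("supply family_ids or covariates with a pair_id column",
           call. = FALSE)
    family_ids <- covariates$pair_id[match(samples, covariates$sample_id)]
  }
  if (ncol(methyl) == 0L)
    return(data.frame(probe = character(0), trait = character(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0),
                      significant = logical(0)))
  X <- build_covar_matrix(covariates, samples)
  rows <- vector("list", ncol(methyl) * length(traits))
  k <- 0L
  for (tr in traits) {
    y <- trait_matrix[, tr]
    for (j in seq_len(ncol(methyl))) {
      k <- k + 1L
      res <- tryCatch(
        fit_random_intercept(y, methyl[, j], X, family_ids),
        error = function(e) e)
      rows[[k]] <- if (inherits(res, "error")) {
        data.frame(probe = colnames(methyl)[j], trait = tr,
                   beta = NA_real_, se = NA_real_, p = NA_real_,
                   error = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        data.frame(probe = colnames(methyl)[j], trait = tr,
                   beta = res$beta, se = res$se, p = res$p, error = NA,
                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (all(is.na(out$error))) out$error <- NULL
  out$significant <- !is.na(out$p) & out$p < threshold
  if (!is.null(annotation)) {
    idx <- match(out$probe, annotation$probe)
    out$chr <- annotation$chr[idx]
    out$position <- annotation$position[idx]
    out$gene <- annotation$gene[idx]
    out <- out[, c("probe", "chr", "position", "gene", "trait",
                   "beta", "se", "p", "significant",
                   intersect("error", names(out)))]
  }
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
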