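#' @export
print.twin_ace <- function(x, digits = 2, ...) {
  cat("Twin ACE variance decomposition (", x$n_mz, " MZ / ", x$n_dz,
      " DZ pairs)\n", sep = "")
  cat("Best model: ", x$model, "\n", sep = "")
  ci <- x$ci
  fmt <- function(cmp) {
    if (is.null(ci) || any(is.na(ci[[cmp]])))
      sprintf("%.*f", digits, x$shares[cmp])
    else format_ci(x$shares[cmp], ci[[cmp]][1], ci[[cmp]][2], digits)
  }
  lab <- c(a2 = "A", c2 = "C", e2 = "E")
  free <- model_free_shares(x$model)
  for (cmp in c("a2", "c2", "e2")) {
    if (cmp %in% free || x$model == "E")
      cat("  ", lab[cmp], " = ", fmt(cmp), "\n", sep = "")
  }
  if (!is.null(x$icc$mz))
    cat("  ICC(MZ) = ",
        format_ci(x$icc$mz$estimate, x$icc$mz$lower, x$icc$mz$upper, digits),
        "\n", sep = "")
  if (!is.null(x$icc$dz))
    cat("  ICC(DZ) = ",
        format_ci(x$icc$dz$estimate, x$icc$dz$lower, x$icc$dz$upper, digits),
        "\n", sep = "")
  invisible(x)
}

#' @export
summary.twin_ace <- function(object, ...) {
  structure(list(fit = object), class = "summary.twin_ace")
}

#' @export
print.summary.twin_ace <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$selection)) {
    cat("\nModel selection (sequential drops from ACE, alpha = ",
        x$fit$alpha, "):\n", sep = "")
    tr <- x$fit$selection$trace
    tr$loglik <- round(tr$loglik, 3)
    tr$aic <- round(tr$aic, 3)
    tr$lrt_p <- signif(tr$lrt_p, 3)
    print(tr, row.names = FALSE)
  }
  invisible(x)
}

#' Standardized variance shares of a twin ACE fit
#' @param object a `twin_ace` fit
#' @param ... unused
#' @return named vector c(a2, c2, e2), summing to 1
#' @export
coef.twin_ace <- function(object, ...) object$shares

#' Profile-likelihood confidence intervals for a twin ACE fit
#' @param object a `twin_ace` fit
#' @param parm components to report (default all free components)
#' @param level confidence level
#' @param ... unused
#' @return matrix with lower/upper columns
#' @export
confint.twin_ace <- function(object, parm = c("a2", "c2", "e2"),
                             level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  ci <- if (!is.null(object$ci) && identical(level, object$level)) object$ci
        else profile_ci_all(object, level)
  out <- t(vapply(parm, function(p) ci[[p]], numeric(2)))
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
logLik.twin_ace <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = 2 * (object$n_mz + object$n_dz),
            class = "logLik")
}

#' Simulate twin pairs from a fitted variance decomposition
#'
#' Draws cohorts of the fitted pair counts from the estimated standardized
#' shares, returning pair tables in the same layout the fitter consumes.
#'
#' @param object a `twin_ace` fit
#' @param nsim number of simulated cohorts
#' @param seed optional seed
#' @param ... unused
#' @return list of `nsim` pair data.frames
#' @export
simulate.twin_ace <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sh <- object$shares
  lapply(seq_len(nsim), function(i) {
    tw <- simulate_twin_trait(object$n_mz, object$n_dz, sh["a2"], sh["c2"])
    data.frame(
      pair_id = sprintf("sim%04d", seq_len(object$n_mz + object$n_dz)),
      zygosity = rep(c("MZ", "DZ"), c(object$n_mz, object$n_dz)),
      value_1 = c(tw$mz[, 1], tw$dz[, 1]),
      value_2 = c(tw$mz[, 2], tw$dz[, 2]),
      stringsAsFactors = FALSE)
  })
}
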