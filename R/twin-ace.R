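# Twin ACE variance decomposition by maximum likelihood.
#
# The likelihood works on standardized, pre-adjusted trait values with means
# profiled out (enforced zero), so each pair contributes a zero-mean bivariate
# normal density with total variance va+vc+ve and cross-twin covariance
# va+vc (MZ) or va/2+vc (DZ). All fits run on per-zygosity sufficient
# statistics (n, sum of squares, sum of cross-products), which makes the
# likelihood O(1) per evaluation regardless of cohort size.

twin_suff <- function(values) {
  values <- values[complete.cases(values), , drop = FALSE]
  list(n = nrow(values),
       SS = sum(values^2),
       SP = sum(values[, 1] * values[, 2]))
}

# log-likelihood contribution of one zygosity group with total variance v and
# cross-twin covariance cv; -Inf when the 2x2 covariance is not positive
# definite (optimizer-safe)
ll_zyg <- function(s, v, cv) {
  if (s$n == 0L) return(0)
  det <- v^2 - cv^2
  if (!is.finite(det) || v <= 0 || det <= 0) return(-Inf)
  -s$n * log(2 * pi) - s$n / 2 * log(det) -
    0.5 * (v * s$SS - 2 * cv * s$SP) / det
}

ll_variances <- function(va, vc, ve, smz, sdz) {
  v <- va + vc + ve
  ll_zyg(smz, v, va + vc) + ll_zyg(sdz, v, 0.5 * va + vc)
}

#' Twin-pair bivariate normal log-likelihood
#'
#' Sum over pairs of the zero-mean bivariate normal log-density with variance
#' a2 + c2 + e2 and cross-twin covariance a2 + c2 (MZ) or a2/2 + c2 (DZ).
#' On the standardized scale the components are variance proportions; the
#' function accepts any nonnegative variances.
#'
#' @param pairs data.frame with columns zygosity ("MZ"/"DZ"), value_1, value_2
#' @param a2,c2,e2 nonnegative variance components
#' @return log-likelihood (scalar; -Inf for non-positive-definite settings)
#' @export
twin_loglik <- function(pairs, a2, c2, e2) {
  if (any(c(a2, c2, e2) < 0))
    stop("variance components must be nonnegative", call. = FALSE)
  pairs <- check_pairs(pairs)
  smz <- twin_suff(as.matrix(pairs[pairs$zygosity == "MZ",
                                   c("value_1", "value_2")]))
  sdz <- twin_suff(as.matrix(pairs[pairs$zygosity == "DZ",
                                   c("value_1", "value_2")]))
  ll_variances(a2, c2, e2, smz, sdz)
}

check_pairs <- function(pairs) {
  need <- c("zygosity", "value_1", "value_2")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("pair table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(pairs$zygosity), c("MZ", "DZ"))
  if (length(bad))
    stop("zygosity must be MZ or DZ; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  pairs
}

model_free <- function(model) {
  switch(model,
         ACE = c("va", "vc", "ve"),
         AE = c("va", "ve"),
         CE = c("vc", "ve"),
         E = "ve",
         stop("unknown model: ", model, call. = FALSE))
}

model_free_shares <- function(model) {
  unname(c(va = "a2", vc = "c2", ve = "e2")[model_free(model)])
}

# constrained ML fit of one submodel from sufficient statistics; three fixed
# deterministic starting points, best kept
fit_model_suff <- function(smz, sdz, model) {
  vt <- (smz$SS + sdz$SS) / (2 * max(smz$n + sdz$n, 1L))
  free <- model_free(model)
  k <- length(free)
  if (model == "E") {
    ve <- vt
    return(list(model = model, variances = c(va = 0, vc = 0, ve = ve),
                loglik = ll_variances(0, 0, ve, smz, sdz),
                k = 1L, aic = -2 * ll_variances(0, 0, ve, smz, sdz) + 2,
                convergence = 0L))
  }
  obj <- function(par) {
    p <- setNames(numeric(3), c("va", "vc", "ve"))
    p[free] <- par
    -ll_variances(p["va"], p["vc"], p["ve"], smz, sdz)
  }
  starts <- list(c(va = 1, vc = 1, ve = 1) / 3,
                 c(va = 0.6, vc = 0.1, ve = 0.3),
                 c(va = 0.1, vc = 0.6, ve = 0.3))
  best <- NULL
  for (s0 in starts) {
    p0 <- vt * s0[free] / sum(s0[free])
    o <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B",
            lower = c(rep(0, k - 1), 1e-10)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    stop("convergence failure for model ", model, call. = FALSE)
  p <- setNames(numeric(3), c("va", "vc", "ve"))
  p[free] <- best$par
  ll <- -best$value
  list(model = model, variances = p, loglik = ll, k = k,
       aic = -2 * ll + 2 * k, convergence = best$convergence)
}

shares_from_variances <- function(v) {
  s <- v / sum(v)
  names(s) <- c("a2", "c2", "e2")
  s
}

#' Fit twin ACE variance-component models
#'
#' Fits the requested submodels of the classical twin ACE decomposition by
#' maximum likelihood on standardized pair values, optionally selects the
#' best-fitting model by sequential likelihood-ratio drops from the full ACE
#' model with AIC arbitration, and computes profile-likelihood confidence
#' intervals and per-zygosity intra-class correlations.
#'
#' Model selection follows the classical recipe: drop C (giving AE), drop A
#' (giving CE) or drop both (giving E) from the full model; a drop is kept
#' when its likelihood-ratio test against ACE is not rejected at `alpha`
#' (chi-square with df = number of dropped components); among the surviving
#' models the lowest AIC wins, ties broken toward fewer parameters and then
#' toward the model retaining A.
#'
#' @param pairs data.frame with columns zygosity ("MZ"/"DZ"), value_1,
#'   value_2; incomplete pairs are dropped
#' @param model "best" (fit all four and select) or one of "ACE", "AE",
#'   "CE", "E"
#' @param alpha significance level of the likelihood-ratio drop tests
#' @param ci compute profile-likelihood intervals for the chosen model
#' @param level confidence level for intervals
#' @param mixture use the 50:50 chi-square(0)/chi-square(1) boundary mixture
#'   reference for single-component drop tests instead of the plain
#'   chi-square (default off, matching common twin-study practice)
#' @return object of class `twin_ace`
#' @examples
#' tw <- simulate_twin_trait(200, 300, a2 = 0.6, c2 = 0.1, seed = 1)
#' pairs <- data.frame(zygosity = rep(c("MZ", "DZ"), c(200, 300)),
#'                     value_1 = c(tw$mz[, 1], tw$dz[, 1]),
#'                     value_2 = c(tw$mz[, 2], tw$dz[, 2]))
#' fit <- twin_ace(pairs)
#' summary(fit)
#' @export
twin_ace <- function(pairs, model = c("best", "ACE", "AE", "CE", "E"),
                     alpha = 0.05, ci = TRUE, level = 0.95,
                     mixture = FALSE) {
  model <- match.arg(model)
  pairs <- check_pairs(pairs)
  mz <- as.matrix(pairs[pairs$zygosity == "MZ", c("value_1", "value_2")])
  dz <- as.matrix(pairs[pairs$zygosity == "DZ", c("value_1", "value_2")])
  smz <- twin_suff(mz)
  sdz <- twin_suff(dz)
  if (model != "E" && (smz$n == 0L || sdz$n == 0L))
    stop("both zygosity groups must be nonempty", call. = FALSE)
  models <- if (model == "best") c("ACE", "AE", "CE", "E") else model
  fits <- lapply(setNames(models, models),
                 function(m) fit_model_suff(smz, sdz, m))
  if (model == "best") {
    sel <- select_best_model(fits, alpha = alpha, mixture = mixture)
    chosen <- sel$model
  } else {
    sel <- NULL
    chosen <- model
  }
  fit <- fits[[chosen]]
  shares <- shares_from_variances(fit$variances)
  # components fixed at zero by the model are exactly zero
  shares[setdiff(c("a2", "c2", "e2"), model_free_shares(chosen))] <- 0
  shares <- shares / sum(shares)
  names(shares) <- c("a2", "c2", "e2")
  obj <- structure(
    list(call = match.call(), model = chosen, shares = shares,
         variances = fit$variances, loglik = fit$loglik, k = fit$k,
         aic = fit$aic, fits = fits, selection = sel,
         n_mz = smz$n, n_dz = sdz$n, suff = list(mz = smz, dz = sdz),
         icc = list(mz = if (smz$n >= 3) twin_icc(mz) else NULL,
                    dz = if (sdz$n >= 3) twin_icc(dz) else NULL),
         alpha = alpha, level = level, ci = NULL),
    class = "twin_ace")
  if (ci) obj$ci <- profile_ci_all(obj, level)
  obj
}

#' Select the best-fitting twin submodel
#'
#' @param fits named list of fits for "ACE", "AE", "CE" and "E" on the same
#'   data (as produced inside [twin_ace()])
#' @param alpha drop-test significance level
#' @param mixture boundary-mixture reference for df = 1 drops
#' @return list with `model`, and `trace` (one row per candidate: loglik,
#'   AIC, LRT df and p against ACE, whether the drop was accepted)
#' @export
select_best_model <- function(fits, alpha = 0.05, mixture = FALSE) {
  need <- c("ACE", "AE", "CE", "E")
  miss <- setdiff(need, names(fits))
  if (length(miss))
    stop("missing submodel fits: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ll_full <- fits$ACE$loglik
  drop_df <- c(ACE = 0L, AE = 1L, CE = 1L, E = 2L)
  trace <- do.call(rbind, lapply(need, function(m) {
    lr <- max(2 * (ll_full - fits[[m]]$loglik), 0)
    p <- if (m == "ACE") NA_real_
         else pchisq(lr, drop_df[m], lower.tail = FALSE)
    if (mixture && !is.na(p) && drop_df[m] == 1L) p <- p / 2
    data.frame(model = m, k = fits[[m]]$k, loglik = fits[[m]]$loglik,
               aic = fits[[m]]$aic, lrt_df = drop_df[m], lrt_p = p,
               stringsAsFactors = FALSE)
  }))
  trace$accepted <- is.na(trace$lrt_p) | trace$lrt_p >= alpha
  surv <- trace[trace$accepted, ]
  # lowest AIC wins; ties toward fewer parameters, then toward retaining A
  ord <- order(round(surv$aic, 10), surv$k,
               match(surv$model, c("ACE", "AE", "CE", "E")))
  list(model = surv$model[ord[1]], trace = trace)
}

#' Intra-class correlation of twin pairs by double entry
#'
#' Pearson correlation of the double-entered pair values (each pair counted
#' in both orders), the twin-literature convention. The confidence interval
#' uses the Fisher z transform with the number of pairs as effective n.
#'
#' @param values n x 2 matrix or data.frame of co-twin values
#' @param level confidence level
#' @return list with `estimate`, `lower`, `upper`, `n_pairs`
#' @export
twin_icc <- function(values, level = 0.95) {
  values <- as.matrix(values)
  values <- values[complete.cases(values), , drop = FALSE]
  n <- nrow(values)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  r <- cor(c(values[, 1], values[, 2]), c(values[, 2], values[, 1]))
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  list(estimate = r, lower = tanh(z - q * se), upper = tanh(z + q * se),
       n_pairs = n)
}

# profiled log-likelihood at a fixed standardized share of one component,
# maximizing over the total variance and the split of the remaining share
profile_loglik_share <- function(obj, component, s) {
  smz <- obj$suff$mz; sdz <- obj$suff$dz
  model <- obj$model
  free <- model_free_shares(model)
  others <- setdiff(free, component)
  vt <- (smz$SS + sdz$SS) / (2 * max(smz$n + sdz$n, 1L))
  shares_at <- function(u) {
    sh <- c(a2 = 0, c2 = 0, e2 = 0)
    sh[component] <- s
    if (length(others) == 1L) {
      sh[others] <- 1 - s
    } else {
      sh[others[1]] <- (1 - s) * u
      sh[others[2]] <- (1 - s) * (1 - u)
    }
    sh
  }
  ll_at <- function(u, logv) {
    sh <- shares_at(u) * exp(logv)
    ll_variances(sh["a2"], sh["c2"], sh["e2"], smz, sdz)
  }
  if (length(others) <= 1L) {
    o <- optimize(function(lv) -ll_at(NA, lv),
                  interval = log(vt) + c(-4, 4))
    -o$objective
  } else {
    o <- optim(c(0.5, log(vt)),
               function(p) -ll_at(p[1], p[2]),
               method = "L-BFGS-B",
               lower = c(1e-9, log(vt) - 6), upper = c(1 - 1e-9, log(vt) + 6))
    -o$value
  }
}

#' Profile-likelihood confidence interval for one variance share
#'
#' The interval collects share values whose profiled log-likelihood lies
#' within qchisq(level, 1)/2 (1.9207 at 95%) of the maximum, truncated to
#' \\[0, 1\\]. Components fixed at zero by the chosen model have no interval.
#'
#' @param object a `twin_ace` fit
#' @param component "a2", "c2" or "e2"
#' @param level confidence level
#' @return numeric c(lower, upper)
#' @export
profile_ci <- function(object, component = c("a2", "c2", "e2"),
                       level = 0.95) {
  component <- match.arg(component)
  free <- model_free_shares(object$model)
  if (!component %in% free) {
    if (object$model == "E" && component == "e2") return(c(1, 1))
    return(c(NA_real_, NA_real_))
  }
  if (object$model == "E") return(c(1, 1))
  shat <- unname(object$shares[component])
  thr <- object$loglik - qchisq(level, 1) / 2
  g <- function(s) profile_loglik_share(object, component, s) - thr
  eps <- 1e-7
  root_between <- function(lo, hi) {
    glo <- g(lo); ghi <- g(hi)
    if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) return(NA_real_)
    uniroot(g, c(lo, hi), tol = 1e-6)$root
  }
  lower <- if (shat <= eps || g(eps) >= 0) 0 else root_between(eps, shat)
  upper <- if (shat >= 1 - eps || g(1 - eps) >= 0) 1
           else root_between(shat, 1 - eps)
  if (is.na(lower) || is.na(upper)) {
    warning("flat profile likelihood; returning [0, 1]", call. = FALSE)
    lower <- if (is.na(lower)) 0 else lower
    upper <- if (is.na(upper)) 1 else upper
  }
  c(max(0, lower), min(1, upper))
}

profile_ci_all <- function(obj, level) {
  out <- lapply(setNames(c("a2", "c2", "e2"), c("a2", "c2", "e2")),
                function(cmp) profile_ci(obj, cmp, level))
  out
}
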