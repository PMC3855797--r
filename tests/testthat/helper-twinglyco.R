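# shared fixtures and independent oracles, built in code

# pair data.frame from simulated co-twin matrices
pairs_from_sim <- function(tw) {
  data.frame(
    zygosity = rep(c("MZ", "DZ"), c(nrow(tw$mz), nrow(tw$dz))),
    value_1 = c(tw$mz[, 1], tw$dz[, 1]),
    value_2 = c(tw$mz[, 2], tw$dz[, 2]),
    stringsAsFactors = FALSE)
}

# brute-force bivariate normal log-density, independent of the fitter
dmvnorm2_log <- function(x, sigma) {
  -log(2 * pi) - 0.5 * log(det(sigma)) -
    0.5 * drop(t(x) %*% solve(sigma) %*% x)
}

# one-way random-effects ANOVA ICC for pairs (k = 2), the classic oracle
anova_icc <- function(values) {
  n <- nrow(values)
  df <- data.frame(y = c(values[, 1], values[, 2]),
                   g = factor(rep(seq_len(n), 2)))
  ms <- anova(stats::aov(y ~ g, data = df))$`Mean Sq`
  (ms[1] - ms[2]) / (ms[1] + ms[2])
}

# exact one-sided hypergeometric tail by log-factorial enumeration
enum_fisher_one_sided <- function(tab) {
  a <- tab[1, 1]; row1 <- sum(tab[1, ]); col1 <- sum(tab[, 1]); n <- sum(tab)
  lchoose_ <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  ks <- max(a, 0):min(row1, col1)
  sum(exp(lchoose_(col1, ks) + lchoose_(n - col1, row1 - ks) -
            lchoose_(n, row1)))
}

# tiny 4-peak annotation: three neutral peaks and one disialylated
toy_annotation <- function() {
  data.frame(
    peak = c("GP1", "GP2", "GP3", "GP4"),
    structure = c("FA2", "A2G1", "FA2BG2S2", "FA2G2"),
    fucosylated = c(1, 0, 1, 1),
    bisecting = c(0, 0, 1, 0),
    gal = c(0, 1, 2, 2),
    sial = c(0, 0, 2, 0),
    stringsAsFactors = FALSE)
}
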