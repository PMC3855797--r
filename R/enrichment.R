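#' Build the 2x2 heritability-class enrichment table
#'
#' Numerators count significant association rows (probe x trait pairs);
#' denominators are the numbers of traits per heritability class, the
#' counting convention of array-wide enrichment summaries. A trait with
#' several hits can therefore push a numerator above its denominator; the
#' complementary cell floors at zero (documented quirk of this convention).
#'
#' @param classifications data.frame with trait, class ("low"/"high")
#' @param associations data.frame with trait and either `significant` or `p`
#' @param threshold p cutoff, used when no `significant` column is present
#' @return 2x2 integer matrix, rows low/high, columns hits / traits - hits
#' @export
build_contingency <- function(classifications, associations,
                              threshold = NULL) {
  sig <- if ("significant" %in% names(associations)) {
    associations[which(associations$significant), , drop = FALSE]
  } else {
    if (is.null(threshold))
      stop("supply a threshold when associations carry no significant flag",
           call. = FALSE)
    associations[which(associations$p < threshold), , drop = FALSE]
  }
  unclassified <- setdiff(sig$trait, classifications$trait)
  if (length(unclassified))
    stop("unclassified trait(s) in association table: ",
         paste(unique(unclassified), collapse = ", "), call. = FALSE)
  cls <- classifications$class[match(sig$trait, classifications$trait)]
  hits <- c(low = sum(cls == "low"), high = sum(cls == "high"))
  sizes <- c(low = sum(classifications$class == "low"),
             high = sum(classifications$class == "high"))
  tab <- cbind(hits = hits, rest = pmax(sizes - hits, 0L))
  storage.mode(tab) <- "integer"
  tab
}

#' One-sided exact enrichment p-value for a 2x2 table
#'
#' Hypergeometric tail probability of observing at least the first row's hit
#' count given the table margins — the exact one-sided test that the first
#' class is enriched for hits.
#'
#' @param table 2x2 matrix of nonnegative integers (rows = classes,
#'   columns = hits / non-hits)
#' @return p-value in (0, 1]
#' @export
fisher_one_sided <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be nonnegative integers", call. = FALSE)
  a <- table[1, 1]
  col1 <- sum(table[, 1])
  row1 <- sum(table[1, ])
  n <- sum(table)
  phyper(a - 1, col1, n - col1, row1, lower.tail = FALSE)
}

#' Compare hit proportions between heritability classes
#'
#' @param table 2x2 matrix as built by [build_contingency()]
#' @return list with per-class percentages (raw and 1-decimal report form),
#'   the one-sided exact p, the Pearson chi-square p, and the odds ratio
#'   (Haldane 0.5 correction when any cell is zero)
#' @export
compare_proportions <- function(table) {
  table <- as.matrix(table)
  rs <- rowSums(table)
  if (any(rs == 0)) stop("zero row sum", call. = FALSE)
  prop <- 100 * table[, 1] / rs
  chisq_p <- suppressWarnings(
    chisq.test(table, correct = FALSE)$p.value)
  t2 <- table
  if (any(t2 == 0)) t2 <- t2 + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(proportions = prop,
       # report form truncates at one decimal (5/12 -> 41.6), the convention
       # used in published enrichment summaries of this kind
       proportions_report = trunc(prop * 10) / 10,
       p_exact = fisher_one_sided(table),
       p_chisq = chisq_p,
       odds_ratio = or)
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test computed from group means, SDs and sizes with the
#' Welch-Satterthwaite degrees of freedom — for comparing groups reported
#' only as mean (SD), as in cohort demographics tables.
#'
#' @param mean1,sd1,n1 first group summary
#' @param mean2,sd2,n2 second group summary
#' @return list with `t`, `df`, `p` (two-sided)
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}
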