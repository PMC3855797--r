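toy_peaks <- function() {
  matrix(c(10, 30, 40, 20), 1, 4,
         dimnames = list("s1", c("GP1", "GP2", "GP3", "GP4")))
}

test_that("neutral percentages renormalize over the neutral peaks", {
  ann <- toy_annotation()
  gpn <- neutral_percentages(toy_peaks(), ann)
  expect_equal(colnames(gpn), c("GP1n", "GP2n", "GP4n"))
  expect_equal(unname(gpn[1, ]), c(16.67, 50.00, 33.33), tolerance = 1e-3)
  expect_equal(unname(rowSums(gpn)), 100, tolerance = 1e-9)

  # all peaks neutral: denominator is the full 100%
  ann2 <- ann; ann2$sial <- 0
  gpn2 <- neutral_percentages(toy_peaks(), ann2)
  expect_equal(unname(gpn2[1, "GP4n"]), 20)

  # non-positive neutral sum yields an error record, not an exception
  pk <- toy_peaks(); pk[1, c("GP1", "GP2", "GP4")] <- 0
  gpn3 <- neutral_percentages(pk, ann)
  expect_true(all(is.na(gpn3[1, ])))
  expect_equal(attr(gpn3, "errors"), "s1")
  expect_error(neutral_percentages(
    matrix(1, 1, 1, dimnames = list("s", "GP99")), ann), "GP99")
})

test_that("the full shipped table sums neutral percentages to 100 per sample", {
  x <- simulate_peak_profiles(50, seed = 21)
  rownames(x) <- paste0("s", 1:50)
  gpn <- neutral_percentages(x, default_peak_annotation())
  expect_equal(unname(rowSums(gpn)), rep(100, 50), tolerance = 1e-6)
})

test_that("group sums follow the feature grammar", {
  ann <- toy_annotation()
  pk <- toy_peaks()
  # conjunction F & B & S2 selects the single matching peak
  pk2 <- pk; pk2[1, "GP3"] <- 3.1
  expect_equal(unname(group_sum(pk2, "FBS2", ann)), 3.1)
  # F-group plus FB-group equals the Ftotal group (disjoint union)
  x <- simulate_peak_profiles(25, seed = 22)
  rownames(x) <- paste0("s", 1:25)
  full <- default_peak_annotation()
  for (tok in list(c("FG2", "FBG2", "FtotalG2"),
                   c("FS1", "FBS1", "FtotalS1"),
                   c("Fn", "FBn", "Fn total"))) {
    expect_equal(group_sum(x, tok[1], full) + group_sum(x, tok[2], full),
                 group_sum(x, tok[3], full), tolerance = 1e-12)
  }
  # neutral basis: FG0n matches fucosylated agalactosylated neutral peaks
  gpn <- neutral_percentages(x, full)
  expect_equal(group_sum(x, "FG0n", full),
               gpn[, "GP1n"] + gpn[, "GP4n"], tolerance = 1e-12)
  expect_error(group_sum(pk, "BG1", ann), "selects no peaks")
  expect_error(parse_group_token("XYZ"), "cannot parse")
})

test_that("trait evaluation matches hand computations and identities", {
  ann <- data.frame(peak = c("P1", "P2"), structure = c("FA2BG2S2", "FA2G2S2"),
                    fucosylated = 1, bisecting = c(1, 0), gal = 2, sial = 2)
  pk <- matrix(c(2, 4), 1, 2, dimnames = list("s", c("P1", "P2")))
  d1 <- data.frame(name = "FBS2/FS2", numerator = "FBS2",
                   denominator = "FS2", scale = "ratio")
  d2 <- data.frame(name = "FBS2/(FS2+FBS2)", numerator = "FBS2",
                   denominator = "FS2+FBS2", scale = "ratio")
  expect_equal(unname(evaluate_trait(d1, pk, ann)), 0.5)
  expect_equal(unname(evaluate_trait(d2, pk, ann)), 1 / 3, tolerance = 1e-9)

  # r/(1+r) identity across random samples
  x <- simulate_peak_profiles(40, seed = 23)
  rownames(x) <- paste0("s", 1:40)
  full <- default_peak_annotation()
  r <- group_sum(x, "FBS2", full) / group_sum(x, "FS2", full)
  expect_equal(unname(evaluate_trait(d2, x, full)), unname(r / (1 + r)),
               tolerance = 1e-12)

  # permille scale: Bn=0.05, Fn=6.0, FBn=1.5 -> 6.667 per mille
  ann3 <- data.frame(peak = c("B1", "F1", "FB1"),
                     structure = c("A2B", "FA2", "FA2B"),
                     fucosylated = c(0, 1, 1), bisecting = c(1, 0, 1),
                     gal = 0, sial = 0)
  pk3 <- matrix(c(0.05, 6.0, 1.5), 1, 3,
                dimnames = list("s", c("B1", "F1", "FB1")))
  d3 <- data.frame(name = "Bn/(Fn + FBn) ‰", numerator = "Bn",
                   denominator = "Fn+FBn", scale = "permille")
  expect_equal(unname(evaluate_trait(d3, pk3, ann3)), 1000 * 0.05 / 7.5,
               tolerance = 1e-9)

  # zero denominator -> NA with a warning, not an error
  pk0 <- matrix(c(1, 0), 1, 2, dimnames = list("s", c("P1", "P2")))
  expect_warning(v <- evaluate_trait(
    data.frame(name = "x", numerator = "FBS2", denominator = "FS2",
               scale = "ratio"), pk0, ann), "zero denominator")
  expect_true(is.na(v))
})

test_that("compute_all_traits yields the 76 standard trait columns", {
  x <- simulate_peak_profiles(30, seed = 24)
  rownames(x) <- paste0("s", 1:30)
  tm <- suppressMessages(compute_all_traits(x))
  expect_equal(ncol(tm), 76)
  expect_true(all(c("GP4", "GP8n", "FBS2/FS2", "Fn total",
                    "Bn/(Fn + FBn) ‰") %in% colnames(tm)))
  expect_false(any(is.na(tm)))

  # empty definitions: peaks only
  empty <- validate_trait_definitions(
    data.frame(name = character(0), numerator = character(0),
               denominator = character(0), scale = character(0)),
    default_peak_annotation())
  expect_equal(ncol(compute_all_traits(x, definitions = empty)), 24)

  # order invariance per sample id
  shuf <- x[sample(nrow(x)), ]
  tm2 <- suppressMessages(compute_all_traits(shuf))
  expect_equal(tm2[rownames(tm), ], tm)

  # duplicate names rejected at load time
  dup <- data.frame(name = c("a", "a"), numerator = "GP4",
                    denominator = "1", scale = "ratio")
  expect_error(validate_trait_definitions(dup, default_peak_annotation()),
               "duplicate")
  # a definition whose token matches nothing is a load error
  bad <- data.frame(name = "b", numerator = "BG1", denominator = "1",
                    scale = "ratio")
  expect_error(validate_trait_definitions(bad, default_peak_annotation()),
               "selects no peaks")
})

test_that("derived ratio traits are invariant to global rescaling of a sample", {
  x <- simulate_peak_profiles(10, seed = 25)
  rownames(x) <- paste0("s", 1:10)
  tm <- suppressMessages(compute_all_traits(x))
  ratio_traits <- setdiff(colnames(tm), paste0("GP", 1:24))
  tm_scaled <- suppressMessages(compute_all_traits(x * 3))
  expect_equal(tm_scaled[, ratio_traits], tm[, ratio_traits],
               tolerance = 1e-9)
})
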