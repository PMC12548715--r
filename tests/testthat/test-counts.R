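test_that("normalization turns counts into per-animal percentages", {
  tab <- cell_count_table(data.frame(
    region = c("A", "A", "B"), animal = c("m1", "m2", "m2"),
    genotype = "vGAT", count = c(100, 25, 75)))
  fr <- normalize_counts(tab)
  expect_equal(fr$fraction_pct[fr$animal == "m1"], 100)
  expect_equal(sort(fr$fraction_pct[fr$animal == "m2"]), c(25, 75))
})

test_that("excluded rows leave numerator and denominator", {
  tab <- cell_count_table(data.frame(
    region = c("A", "B", "spread"), animal = "m1", genotype = "vGAT",
    count = c(25, 25, 50), excluded = c(FALSE, FALSE, TRUE)))
  fr <- normalize_counts(tab)
  expect_equal(sort(fr$fraction_pct), c(50, 50))
  expect_false("spread" %in% fr$region)
})

test_that("zero-total animals are reported by name", {
  tab <- cell_count_table(data.frame(
    region = "A", animal = c("m1", "m2"), genotype = "vGAT",
    count = c(10, 0)))
  expect_error(normalize_counts(tab), "m2")
})

test_that("per-animal fractions plus remainder always sum to 100", {
  fr_list <- pvt_input_fractions()
  tab <- generate_count_table(lapply(fr_list, `/`, 100),
                              totals = list(vGLUT2 = 476, vGAT = 469),
                              n_animals = 3L, seed = 4L)
  fr <- normalize_counts(tab)
  for (an in unique(fr$animal))
    expect_equal(sum(fr$fraction_pct[fr$animal == an]), 100,
                 tolerance = 1e-9)
})

test_that("region summaries use the closed-form mean and SEM", {
  fr <- data.frame(region = "LH", animal = c("m1", "m2", "m3"),
                   genotype = "vGAT", count = 0,
                   fraction_pct = c(10, 12, 14))
  s <- summarize_regions(fr)
  expect_equal(s$mean_pct[s$region == "LH"], 12)
  expect_equal(s$sem_pct[s$region == "LH"], 2 / sqrt(3), tolerance = 1e-9)
})

test_that("regions below the reporting threshold are pooled", {
  fr <- data.frame(region = rep(c("big", "tiny"), each = 2),
                   animal = rep(c("m1", "m2"), 2), genotype = "vGAT",
                   count = 0, fraction_pct = c(97.1, 97.1, 2.9, 2.9))
  s <- summarize_regions(fr, min_report_pct = 3)
  expect_false("tiny" %in% s$region)
  expect_equal(s$mean_pct[s$region == "scattered/other"], 2.9)
})

test_that("the listed glutamatergic regions sum to the published coverage", {
  v <- pvt_input_fractions()$vGLUT2
  fr <- data.frame(region = names(v), animal = "m1", genotype = "vGLUT2",
                   count = 0, fraction_pct = unname(v))
  s <- summarize_regions(fr)
  cov <- coverage_summary(s)
  expect_equal(cov$listed_pct, 77.75, tolerance = 1e-9)
  expect_equal(cov$remainder_pct, 22.25, tolerance = 1e-9)
})

test_that("phenotype classification implements the 0.2 / 5 ratio rule", {
  expect_equal(classify_region(0.18, 1), "GABAergic")   # LH-style ratio 0.18
  expect_equal(classify_region(1, 1), "mixed")
  expect_equal(classify_region(6, 1), "glutamatergic")
  # closed boundaries are mixed
  expect_equal(classify_region(0.2, 1), "mixed")
  expect_equal(classify_region(5, 1), "mixed")
  # one-sided zeros hit the extremes
  expect_equal(classify_region(3, 0), "glutamatergic")
  expect_equal(classify_region(0, 3), "GABAergic")
  expect_error(classify_region(0, 0), "both fractions zero")
})

test_that("classification is invariant to rescaling both fractions", {
  set.seed(8)
  for (rep in 1:20) {
    a <- runif(1, 0.01, 20); b <- runif(1, 0.01, 20)
    k <- runif(1, 0.001, 1000)
    expect_identical(classify_region(a * k, b * k), classify_region(a, b))
  }
})

test_that("coverage summary reproduces the published remainder arithmetic", {
  fl <- pvt_input_fractions()
  fr <- do.call(rbind, lapply(names(fl), function(g)
    data.frame(region = names(fl[[g]]), animal = paste0(g, "_m1"),
               genotype = g, count = 0, fraction_pct = unname(fl[[g]]))))
  cov <- coverage_summary(summarize_regions(fr))
  expect_equal(cov$listed_pct[cov$genotype == "vGAT"], 78.63,
               tolerance = 1e-9)
  expect_equal(cov$remainder_pct[cov$genotype == "vGAT"], 21.37,
               tolerance = 1e-9)
  expect_equal(cov$remainder_pct[cov$genotype == "vGLUT2"], 22.25,
               tolerance = 1e-9)
  # single region holding everything leaves no remainder
  one <- data.frame(region = "A", genotype = "vGAT", mean_pct = 100)
  expect_equal(coverage_summary(one)$remainder_pct, 0)
})

test_that("double-label percentages follow the printed arithmetic", {
  expect_equal(double_label_fraction(501, 519), 96.53)
  expect_equal(double_label_fraction(0, 10), 0)
  expect_equal(double_label_fraction(519, 519), 100)
  expect_error(double_label_fraction(5, 0), "positive")
  expect_error(double_label_fraction(11, 10), "n_double <= n_total")
})

test_that("generated tables round-trip to their generating fractions", {
  fl <- lapply(pvt_input_fractions(), `/`, 100)
  tab <- generate_count_table(fl, totals = list(vGLUT2 = 476, vGAT = 469),
                              n_animals = 3L, seed = 10L)
  s <- summarize_regions(normalize_counts(tab))
  totals <- c(vGLUT2 = 476, vGAT = 469)
  for (g in names(fl)) {
    for (r in names(fl[[g]])) {
      row <- s[s$region == r & s$genotype == g, ]
      expect_equal(nrow(row), 1L)
      # oracle: multinomial standard error of the 3-animal mean
      p <- fl[[g]][[r]]
      sem <- 100 * sqrt(p * (1 - p) / totals[[g]]) / sqrt(3)
      expect_lt(abs(row$mean_pct - 100 * p), 3 * sem)
    }
  }
})
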