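#' Cell-count table for retrograde tracing experiments
#'
#' Validates and normalises a long-format table of retrogradely labeled
#' cell counts: one row per (region, animal, genotype). An `excluded`
#' flag marks rows attributed to tracer spread; excluded rows take part in
#' neither the numerator nor the denominator of any fraction.
#'
#' @param x data frame with columns `region`, `animal`, `genotype`,
#'   `count` and optionally `excluded` (default `FALSE`).
#' @return the validated data frame with class `CellCountTable`.
#' @export
cell_count_table <- function(x) {
  need <- c("region", "animal", "genotype", "count")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("need columns region, animal, genotype, count")
  if (is.null(x$excluded)) x$excluded <- FALSE
  if (any(x$count < 0) || any(x$count != round(x$count)))
    stop("counts must be non-negative integers")
  key <- paste(x$region, x$animal, x$genotype)
  if (anyDuplicated(key))
    stop("(region, animal, genotype) rows must be unique")
  x$region <- as.character(x$region)
  x$animal <- as.character(x$animal)
  x$genotype <- as.character(x$genotype)
  class(x) <- c("CellCountTable", "data.frame")
  x
}

#' Normalize counts to per-animal percentages of the subcortical total
#'
#' Each animal's region counts are expressed as a percentage of that
#' animal's total labeled cells (excluded rows dropped from both sides of
#' the ratio).
#'
#' @param table a [cell_count_table()].
#' @return data frame (region, animal, genotype, count, fraction_pct).
#' @export
normalize_counts <- function(table) {
  table <- cell_count_table(as.data.frame(table))
  tab <- table[!table$excluded, , drop = FALSE]
  totals <- tapply(tab$count, tab$animal, sum)
  if (any(totals == 0))
    stop("animal(s) with zero total cells: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  tab$fraction_pct <- 100 * tab$count / as.numeric(totals[tab$animal])
  rownames(tab) <- NULL
  class(tab) <- "data.frame"
  tab
}

#' Classify a region's afferent phenotype from genotype fractions
#'
#' The call is based on the ratio r = vGLUT2 fraction / vGAT fraction:
#' r < `low` (five-fold GABAergic dominance at the default 0.2) gives
#' "GABAergic", r > `high` (default 5) gives "glutamatergic", and the
#' closed interval \[low, high\] gives "mixed". One-sided zero fractions
#' map to the corresponding extreme; the call is invariant to rescaling
#' both fractions by the same positive constant.
#'
#' @param vglut2_frac,vgat_frac non-negative fractions (any common scale).
#' @param low,high ratio thresholds.
#' @return one of "GABAergic", "mixed", "glutamatergic" (vectorised).
#' @export
classify_region <- function(vglut2_frac, vgat_frac, low = 0.2, high = 5) {
  n <- max(length(vglut2_frac), length(vgat_frac))
  vglut2_frac <- rep_len(vglut2_frac, n)
  vgat_frac <- rep_len(vgat_frac, n)
  if (any(vglut2_frac < 0) || any(vgat_frac < 0))
    stop("fractions must be non-negative")
  if (any(vglut2_frac == 0 & vgat_frac == 0))
    stop("region with both fractions zero is not a valid input region")
  r <- ifelse(vgat_frac == 0, Inf, vglut2_frac / vgat_frac)
  ifelse(r < low, "GABAergic",
         ifelse(r > high, "glutamatergic", "mixed"))
}

#' Summarize region fractions across animals
#'
#' Per region and genotype: mean percentage and SEM across animals
#' (n - 1 standard deviation). Regions whose mean stays below
#' `min_report_pct` in every genotype are pooled into "scattered/other",
#' mirroring the >3 percent reporting rule used for afferent maps. When
#' both genotypes are present the phenotype of each listed region is
#' called with [classify_region()].
#'
#' @param fractions output of [normalize_counts()].
#' @param min_report_pct reporting threshold (percent of total cells).
#' @param low,high ratio thresholds passed to [classify_region()].
#' @return data frame of class `RegionSummary`
#'   (region, genotype, mean_pct, sem_pct, n, phenotype, ratio).
#' @export
summarize_regions <- function(fractions, min_report_pct = 3,
                              low = 0.2, high = 5) {
  stopifnot(all(c("region", "genotype", "fraction_pct") %in% names(fractions)))
  agg <- do.call(rbind, lapply(
    split(fractions, list(fractions$region, fractions$genotype), drop = TRUE),
    function(d) {
      n <- nrow(d)
      data.frame(region = d$region[1], genotype = d$genotype[1],
                 mean_pct = mean(d$fraction_pct),
                 sem_pct = if (n > 1) stats::sd(d$fraction_pct) / sqrt(n) else NA_real_,
                 n = n)
    }))
  rownames(agg) <- NULL
  # pooling: a region is listed if it clears the threshold in any genotype
  listed <- unique(agg$region[agg$mean_pct > min_report_pct])
  listed <- setdiff(listed, "scattered")
  pooled <- agg[!(agg$region %in% listed), , drop = FALSE]
  agg <- agg[agg$region %in% listed, , drop = FALSE]
  if (nrow(pooled)) {
    pool <- do.call(rbind, lapply(split(pooled, pooled$genotype), function(d)
      data.frame(region = "scattered/other", genotype = d$genotype[1],
                 mean_pct = sum(d$mean_pct), sem_pct = NA_real_,
                 n = max(d$n))))
    agg <- rbind(agg, pool)
  }
  agg$phenotype <- NA_character_
  agg$ratio <- NA_real_
  gts <- unique(agg$genotype)
  if (all(c("vGAT", "vGLUT2") %in% gts)) {
    for (r in setdiff(unique(agg$region), "scattered/other")) {
      vg <- agg$mean_pct[agg$region == r & agg$genotype == "vGLUT2"]
      va <- agg$mean_pct[agg$region == r & agg$genotype == "vGAT"]
      vg <- if (length(vg)) vg else 0
      va <- if (length(va)) va else 0
      if (vg == 0 && va == 0) next
      agg$ratio[agg$region == r] <- if (va == 0) Inf else vg / va
      agg$phenotype[agg$region == r] <- classify_region(vg, va, low, high)
    }
  }
  rownames(agg) <- NULL
  class(agg) <- c("RegionSummary", "data.frame")
  agg
}

#' Listed vs scattered coverage per genotype
#'
#' Sums the listed-region mean percentages per genotype and reports the
#' remainder (100 - listed), i.e. the share of labeled cells scattered
#' outside the individually reported regions.
#'
#' @param summary a [summarize_regions()] result, or any data frame with
#'   columns region, genotype, mean_pct.
#' @return data frame (genotype, listed_pct, remainder_pct).
#' @export
coverage_summary <- function(summary) {
  stopifnot(all(c("region", "genotype", "mean_pct") %in% names(summary)))
  listed <- summary[summary$region != "scattered/other", , drop = FALSE]
  out <- do.call(rbind, lapply(split(listed, listed$genotype), function(d)
    data.frame(genotype = d$genotype[1],
               listed_pct = sum(d$mean_pct),
               remainder_pct = 100 - sum(d$mean_pct))))
  rownames(out) <- NULL
  out
}

#' Double-labeling percentage
#'
#' Share of neurons positive for a second marker among all labeled
#' neurons, as a percentage rounded to two decimals (e.g. 501 of 519
#' mCherry cells calretinin-immunoreactive -> 96.53).
#'
#' @param n_double,n_total counts with `0 <= n_double <= n_total`,
#'   `n_total > 0`.
#' @return percentage, rounded to 2 decimals.
#' @export
double_label_fraction <- function(n_double, n_total) {
  if (any(n_total <= 0)) stop("`n_total` must be positive")
  if (any(n_double < 0) || any(n_double > n_total))
    stop("need 0 <= n_double <= n_total")
  round(100 * n_double / n_total, 2)
}
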