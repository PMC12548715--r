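#' Correlation with two-sided p-value
#'
#' Pearson product-moment or Spearman rank correlation between two
#' measurement vectors (e.g. per-ROI axon density vs calretinin
#' intensity), with the usual t-transform two-sided p-value.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, with
#'   non-zero variance.
#' @param method "pearson" or "spearman".
#' @return list of class `CorrelationResult`: `method`, `r`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  structure(list(method = method, r = unname(ct$estimate),
                 p = ct$p.value, n = length(x)),
            class = "CorrelationResult")
}

#' Student's t-test (pooled-variance unpaired, or paired)
#'
#' @param a,b numeric vectors; for `paired = TRUE` equal lengths >= 2,
#'   otherwise each of length >= 2.
#' @param paired paired or two-sample design.
#' @return list of class `TTestResult`: `t`, `df`, `p`, `paired`.
#' @export
ttest_groups <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b) || length(a) < 2L)
      stop("paired test needs equal lengths >= 2")
  } else if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs n >= 2")
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = !paired)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, paired = paired),
            class = "TTestResult")
}

tukey_pairs_df <- function(means, labels, ms_error, df_error, n_per) {
  pairs <- utils::combn(seq_along(means), 2)
  k <- length(means)
  data.frame(
    pair = apply(pairs, 2, function(p)
      paste(labels[p[2]], labels[p[1]], sep = "-")),
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    p_adj = vapply(seq_len(ncol(pairs)), function(i) {
      p <- pairs[, i]
      se <- sqrt(ms_error / 2 * (1 / n_per[p[1]] + 1 / n_per[p[2]]))
      q <- abs(means[p[2]] - means[p[1]]) / se
      stats::ptukey(q, k, df_error, lower.tail = FALSE)
    }, numeric(1))
  )
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Standard fixed-effects decomposition (via [stats::aov()]) of
#' independent groups, followed by Tukey's honestly-significant-
#' difference pairwise comparisons.
#'
#' @param groups either a named list of numeric vectors, or a numeric
#'   vector (then `g` gives the grouping factor).
#' @param g grouping factor when `groups` is a vector.
#' @param tukey run the post hoc (set `FALSE` to skip, e.g. in
#'   simulations).
#' @return list of class `AnovaResult`: `design = "one_way"`, `F`,
#'   `df1`, `df2`, `p`, and `tukey` (pair, diff, p_adj) when requested.
#' @export
anova_oneway <- function(groups, g = NULL, tukey = TRUE) {
  if (is.list(groups)) {
    if (is.null(names(groups)))
      names(groups) <- paste0("g", seq_along(groups))
    values <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)),
                levels = names(groups))
  } else {
    values <- groups
    g <- factor(g)
  }
  n_per <- table(g)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(n_per < 2L))
    stop("every group needs n >= 2 (offending: ",
         paste(names(n_per)[n_per < 2], collapse = ", "), ")")
  fit <- stats::aov(values ~ g)
  sm <- summary(fit)[[1]]
  res <- list(design = "one_way",
              F = sm$`F value`[1], df1 = sm$Df[1], df2 = sm$Df[2],
              p = sm$`Pr(>F)`[1])
  if (tukey) {
    th <- stats::TukeyHSD(fit)$g
    res$tukey <- data.frame(pair = rownames(th), diff = th[, "diff"],
                            p_adj = th[, "p adj"], row.names = NULL)
  }
  structure(res, class = "AnovaResult")
}

# Greenhouse-Geisser epsilon from the covariance matrix of the
# condition columns (k conditions).
gg_epsilon <- function(S) {
  k <- ncol(S)
  sbar_d <- mean(diag(S))
  sbar <- mean(S)
  rowm <- rowMeans(S)
  num <- (k * (sbar_d - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * sbar^2)
  eps <- num / den
  min(max(eps, 1 / (k - 1)), 1)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject decomposition of a complete subjects x conditions
#' grid. The F statistic uses the subject-by-condition interaction as
#' error; the p-value applies the Greenhouse-Geisser sphericity
#' correction to both degrees of freedom (reported as the fractional
#' `df1`/`df2`). Tukey pairwise comparisons use the interaction mean
#' square with its uncorrected df.
#'
#' @param data numeric matrix, rows = subjects, columns = conditions
#'   (complete; >= 2 subjects and >= 2 conditions).
#' @param tukey run the post hoc.
#' @return list of class `AnovaResult`: `design = "repeated_measures"`,
#'   `F`, `df1`, `df2` (GG-corrected), `epsilon`, `p`, `tukey`.
#' @export
anova_rm <- function(data, tukey = TRUE) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("repeated-measures design must be complete")
  n <- nrow(data); k <- ncol(data)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  grand <- mean(data)
  ss_cond <- n * sum((colMeans(data) - grand)^2)
  ss_subj <- k * sum((rowMeans(data) - grand)^2)
  ss_tot <- sum((data - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  Fv <- ms_cond / ms_err
  eps <- gg_epsilon(stats::cov(data))
  p <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
  res <- list(design = "repeated_measures", F = Fv,
              df1 = eps * df1, df2 = eps * df2, epsilon = eps, p = p)
  if (tukey) {
    labs <- colnames(data)
    if (is.null(labs)) labs <- paste0("c", seq_len(k))
    res$tukey <- tukey_pairs_df(colMeans(data), labs, ms_err, df2,
                                rep(n, k))
  }
  structure(res, class = "AnovaResult")
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat(sprintf("%s ANOVA: F(%.4g, %.4g) = %.4g, p = %.4g\n",
              gsub("_", "-", x$design), x$df1, x$df2, x$F, x$p))
  if (!is.null(x$tukey)) {
    cat("Tukey post hoc:\n")
    print(x$tukey, row.names = FALSE)
  }
  invisible(x)
}
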