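#' Per-feature two-group differential abundance tests
#'
#' For each feature, compares its relative abundance between two groups with
#' the gated t-test / Wilcoxon procedure (see [choose_two_sample_test()]) and
#' applies a Bonferroni correction whose family is the full set of features
#' tested in the table.
#'
#' @param composition numeric matrix (features x samples) of relative
#'   abundances.
#' @param groups two-level factor (or character vector) of group labels, one
#'   per sample; each group needs at least 3 samples.
#' @param gate_alpha gate level for the test-selection procedure.
#' @return A data frame with one row per feature: `feature`, `test`,
#'   `statistic`, `raw_p`, `adjusted_p` (`= min(1, raw_p * m)`), and
#'   per-group means and medians.
#' @export
per_feature_tests <- function(composition, groups, gate_alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop2("'groups' must have exactly two levels")
  if (length(groups) != ncol(composition))
    stop2("'groups' must have one label per sample")
  if (any(table(groups) < 3L))
    stop2("each group needs at least 3 samples")
  g1 <- groups == levels(groups)[1L]
  m <- nrow(composition)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    x <- composition[i, g1]
    y <- composition[i, !g1]
    res <- run_two_sample_test(x, y, gate_alpha)
    rows[[i]] <- data.frame(
      feature = rownames(composition)[i] %||% as.character(i),
      test = res$test, statistic = res$statistic, raw_p = res$p_value,
      mean_1 = mean(x), mean_2 = mean(y),
      median_1 = median(x), median_2 = median(y),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- pmin(1, out$raw_p * m)
  out <- out[, c("feature", "test", "statistic", "raw_p", "adjusted_p",
                 "mean_1", "mean_2", "median_1", "median_2")]
  attr(out, "groups") <- levels(groups)
  out
}

#' Median and confidence interval of all pairwise differences
#'
#' Forms all `n1 * n2` differences `x_i - y_j` between two samples and
#' summarizes them by their median together with a distribution-free
#' confidence interval based on the order statistics of the sorted
#' differences at Wilcoxon rank-sum critical values (the Moses interval; the
#' median of pairwise differences is the Hodges-Lehmann shift estimate).
#'
#' @param x,y numeric vectors (each non-empty).
#' @param confidence confidence level of the interval (default 0.95).
#' @return A list of class `median_diff_ci` with `n1`, `n2`,
#'   `n_differences` (`= n1 * n2`), `median`, `lower`, `upper`,
#'   `confidence`.
#' @export
pairwise_difference_summary <- function(x, y, confidence = 0.95) {
  if (length(x) < 1L || length(y) < 1L)
    stop2("'x' and 'y' must be non-empty")
  if (confidence <= 0 || confidence >= 1)
    stop2("'confidence' must lie in (0, 1)")
  n1 <- length(x)
  n2 <- length(y)
  diffs <- sort(as.vector(outer(x, y, "-")))
  alpha <- 1 - confidence
  qu <- qwilcox(alpha / 2, n1, n2)
  if (qu == 0) qu <- 1
  structure(list(n1 = n1, n2 = n2, n_differences = n1 * n2,
                 median = median(diffs),
                 lower = diffs[qu],
                 upper = diffs[n1 * n2 - qu + 1],
                 confidence = confidence),
            class = "median_diff_ci")
}

#' @export
print.median_diff_ci <- function(x, ...) {
  cat("<median_diff_ci> ", x$n_differences, " differences (", x$n1, " x ",
      x$n2, ")\n  median ", signif(x$median, 4), ", ",
      round(100 * x$confidence), "% CI [", signif(x$lower, 4), ", ",
      signif(x$upper, 4), "]\n", sep = "")
  invisible(x)
}

#' Two-class LDA effect-size screen (LEfSe-style)
#'
#' Detects features that are both statistically different between two
#' classes and carry a large linear-discriminant effect size. Abundances are
#' first scaled to a per-sample total of one million; features are screened
#' by a Kruskal-Wallis test at `alpha` (equivalent to the Wilcoxon rank-sum
#' test for two classes); for surviving features the effect size is
#' estimated over bootstrap iterations, each fitting an LDA on a stratified
#' subsample: the per-iteration effect of a feature is the mean of (i) the
#' absolute class-mean difference of the feature's component of the
#' (unit-norm) discriminant projection and (ii) its raw absolute class-mean
#' difference. The reported score is `log10(1 + mean effect)` and a feature
#' is flagged when the screen passes and the score exceeds `lda_threshold`.
#'
#' @param composition numeric matrix (features x samples); any per-sample
#'   scale is accepted and normalized away.
#' @param groups two-level class label per sample (each class >= 3 samples).
#' @param alpha screening level (default 0.05).
#' @param lda_threshold score threshold on the log10 scale (default 4).
#' @param n_boot bootstrap iterations (default 30).
#' @param boot_fraction fraction of each class drawn per iteration
#'   (default 2/3).
#' @param seed optional integer seed.
#' @param max_retries bootstrap redraws allowed when an LDA fit is degenerate.
#' @return A data frame with one row per feature: `feature`, `screen_p`,
#'   `lda_score` (log10; `NA` for features failing the screen), `enriched`
#'   (class with the higher mean) and `pass`.
#' @export
lefse_two_class <- function(composition, groups, alpha = 0.05,
                            lda_threshold = 4, n_boot = 30L,
                            boot_fraction = 2 / 3, seed = NULL,
                            max_retries = 5L) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop2("'groups' must have exactly two classes")
  if (length(groups) != ncol(composition))
    stop2("'groups' must have one label per sample")
  if (any(table(groups) < 3L)) stop2("each class needs at least 3 samples")
  if (boot_fraction <= 0 || boot_fraction > 1)
    stop2("'boot_fraction' must lie in (0, 1]")

  # per-sample normalization to 1e6 makes the screen and effect sizes
  # invariant to the input scale
  totals <- colSums(composition)
  if (any(totals <= 0)) stop2("every sample needs a positive total")
  x <- sweep(composition, 2L, totals, "/") * 1e6

  m <- nrow(x)
  feats <- rownames(x) %||% as.character(seq_len(m))
  screen_p <- vapply(seq_len(m), function(i) {
    v <- x[i, ]
    if (length(unique(v)) == 1L) return(1) # constant feature: no evidence
    suppressWarnings(kruskal.test(v, groups)$p.value)
  }, numeric(1))
  survivors <- which(screen_p < alpha)

  lda_score <- rep(NA_real_, m)
  lv <- levels(groups)
  mean_diff <- rowMeans(x[, groups == lv[1L], drop = FALSE]) -
    rowMeans(x[, groups == lv[2L], drop = FALSE])
  enriched <- ifelse(mean_diff >= 0, lv[1L], lv[2L])

  if (length(survivors)) {
    xs <- t(x[survivors, , drop = FALSE]) # samples x features
    idx_by_class <- split(seq_along(groups), groups)
    draw_sizes <- vapply(idx_by_class, function(ii)
      max(2, ceiling(boot_fraction * length(ii))), numeric(1))
    runs <- function() {
      eff <- matrix(0, n_boot, length(survivors))
      for (b in seq_len(n_boot)) {
        for (attempt in seq_len(max_retries + 1L)) {
          take <- unlist(lapply(names(idx_by_class), function(cl)
            sample(idx_by_class[[cl]], draw_sizes[[cl]])))
          xb <- xs[take, , drop = FALSE]
          yb <- droplevels(groups[take])
          if (nlevels(yb) < 2L) next
          raw <- abs(colMeans(xb[yb == lv[1L], , drop = FALSE]) -
                       colMeans(xb[yb == lv[2L], , drop = FALSE]))
          w <- rep(0, ncol(xb))
          keep <- which(apply(xb, 2L, sd) > 0)
          fit <- NULL
          if (length(keep))
            fit <- tryCatch(
              suppressWarnings(MASS::lda(xb[, keep, drop = FALSE], yb)),
              error = function(e) NULL)
          if (!is.null(fit)) {
            wk <- fit$scaling[, 1L]
            nrm <- sqrt(sum(wk^2))
            if (nrm > 0) w[keep] <- wk / nrm
          } else if (attempt <= max_retries) {
            next # degenerate subsample: redraw
          }
          proj <- sweep(xb, 2L, w, "*")
          pd <- abs(colMeans(proj[yb == lv[1L], , drop = FALSE]) -
                      colMeans(proj[yb == lv[2L], , drop = FALSE]))
          eff[b, ] <- (pd + raw) / 2
          break
        }
      }
      eff
    }
    eff <- if (is.null(seed)) runs() else with_seed(seed, runs())
    lda_score[survivors] <- log10(1 + colMeans(eff))
  }

  data.frame(feature = feats, screen_p = screen_p, lda_score = lda_score,
             enriched = enriched,
             pass = !is.na(lda_score) & screen_p < alpha &
               lda_score > lda_threshold,
             stringsAsFactors = FALSE)
}
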