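#' Shannon diversity index
#'
#' Computes the Shannon index of a single sample's composition in log base 2:
#' `-sum(p_i * log2(p_i))`, with zero entries contributing nothing. The index
#' is non-negative and maximized at `log2(m)` by the uniform composition over
#' `m` features.
#'
#' @param p numeric vector of relative abundances (non-negative, summing to 1
#'   within `1e-9`).
#' @return The Shannon index (a non-negative scalar).
#' @export
#' @examples
#' shannon_index(rep(0.25, 4)) # == 2
shannon_index <- function(p) {
  p <- check_composition(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon index of every sample in a composition matrix
#'
#' @param composition numeric matrix (features x samples) with columns
#'   summing to 1, e.g. from [relative_abundance()].
#' @return Named numeric vector of per-sample Shannon indices.
#' @export
shannon_per_sample <- function(composition) {
  apply(composition, 2L, shannon_index)
}

#' Choose between the t-test and the Wilcoxon rank-sum test
#'
#' Implements the gate used throughout the pipeline: Shapiro-Wilk normality
#' is tested in each group and homogeneity of variance across groups with
#' Levene's test. The two-sample t-test is chosen only if both normality
#' gates and the variance gate pass at `gate_alpha`; otherwise the Wilcoxon
#' rank-sum test is used. Constant groups (for which Shapiro-Wilk is
#' undefined) force the Wilcoxon path with a note.
#'
#' @param x,y numeric vectors, each of length >= 3.
#' @param gate_alpha significance level of the gates (default 0.05).
#' @param levene_center `"mean"` for the classic Levene test (default) or
#'   `"median"` for the Brown-Forsythe variant.
#' @return A list of class `test_choice` with elements `test` (`"t-test"` or
#'   `"wilcoxon"`), `shapiro_p` (length-2 vector), `levene_p`, `gate_alpha`
#'   and `note`.
#' @export
choose_two_sample_test <- function(x, y, gate_alpha = 0.05,
                                   levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  if (length(x) < 3L || length(y) < 3L)
    stop2("both groups need at least 3 observations")
  constant <- function(v) isTRUE(sd(v) == 0) || length(unique(v)) == 1L
  if (constant(x) || constant(y)) {
    return(structure(list(test = "wilcoxon",
                          shapiro_p = c(NA_real_, NA_real_),
                          levene_p = NA_real_, gate_alpha = gate_alpha,
                          note = "constant group; Shapiro-Wilk undefined"),
                     class = "test_choice"))
  }
  sp <- c(shapiro.test(x)$p.value, shapiro.test(y)$p.value)
  grp <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lev <- car::leveneTest(c(x, y) ~ grp,
                         center = if (levene_center == "mean") mean else median)
  lp <- lev[1, "Pr(>F)"]
  use_t <- all(sp > gate_alpha) && lp > gate_alpha
  structure(list(test = if (use_t) "t-test" else "wilcoxon",
                 shapiro_p = sp, levene_p = lp, gate_alpha = gate_alpha,
                 note = NULL),
            class = "test_choice")
}

#' @export
print.test_choice <- function(x, ...) {
  cat("<test_choice> ", x$test,
      " (Shapiro p = ", paste(signif(x$shapiro_p, 3), collapse = ", "),
      "; Levene p = ", signif(x$levene_p, 3), ")\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

# Run the gated two-sample comparison and return test, statistic, p.
run_two_sample_test <- function(x, y, gate_alpha = 0.05,
                                levene_center = "mean") {
  if (length(unique(c(x, y))) == 1L) {
    # identical constant groups: no evidence against the null
    return(list(test = "wilcoxon", statistic = NA_real_, p_value = 1,
                choice = NULL))
  }
  choice <- choose_two_sample_test(x, y, gate_alpha, levene_center)
  if (choice$test == "t-test") {
    ht <- t.test(x, y, var.equal = TRUE)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y))
  }
  list(test = choice$test, statistic = unname(ht$statistic),
       p_value = ht$p.value, choice = choice)
}

alpha_comparison_groups <- function(metadata) {
  male <- metadata$gender == "M"
  st <- metadata$occupation == "student"
  list(
    "MLa vs MSt" = list(a = male & !st, b = male & st),
    "FSt vs MSt" = list(a = !male & st, b = male & st),
    "MLa vs FSt" = list(a = male & !st, b = !male & st),
    "male smokers vs non-smokers" = list(a = male & metadata$smoking == "yes",
                                         b = male & metadata$smoking == "no"),
    "male drinkers vs non-drinkers" = list(a = male & metadata$drinking == "yes",
                                           b = male & metadata$drinking == "no"))
}

#' Compare Shannon alpha diversity across cohort groups
#'
#' For each annotation table and each sample type, computes per-sample
#' Shannon indices and performs the five standard comparisons: laborers vs.
#' male students, female vs. male students, laborers vs. female students,
#' male smokers vs. non-smokers, and male drinkers vs. non-drinkers. Each
#' comparison uses [choose_two_sample_test()] on the Shannon indices.
#' P-values are Bonferroni-adjusted within each annotation-by-sample-type
#' family.
#'
#' @param tables a [feature_table()] or a named list of them (one per
#'   annotation method).
#' @param metadata sample metadata covering all samples.
#' @param gate_alpha gate level passed to [choose_two_sample_test()].
#' @param family_size Bonferroni family size; defaults to 5 (the number of
#'   planned comparisons). Use `NULL` to adjust by the number of comparisons
#'   actually performed.
#' @return A data frame with one row per comparison per sample type per
#'   annotation: `annotation`, `sample_type`, `comparison`, `n1`, `n2`,
#'   `test`, `statistic`, `raw_p`, `adjusted_p`. Comparisons with fewer than
#'   3 samples in a group are skipped with a warning.
#' @export
compare_alpha_across_groups <- function(tables, metadata, gate_alpha = 0.05,
                                        family_size = 5L) {
  if (inherits(tables, "feature_table")) tables <- list(table = tables)
  metadata <- validate_metadata(metadata)
  out <- list()
  for (ann in names(tables)) {
    tab <- tables[[ann]]
    ids <- sample_ids(tab)
    meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
    if (anyNA(meta$sample_id))
      stop2("metadata does not cover all samples of table '", ann, "'")
    for (stype in unique(meta$sample_type)) {
      sel <- meta$sample_type == stype
      comp <- relative_abundance(tab$counts[, sel, drop = FALSE])
      sh <- shannon_per_sample(comp)
      sub <- meta[sel, , drop = FALSE]
      groups <- alpha_comparison_groups(sub)
      rows <- list()
      for (cmp in names(groups)) {
        a <- sh[groups[[cmp]]$a]
        b <- sh[groups[[cmp]]$b]
        if (length(a) < 3L || length(b) < 3L) {
          warning("skipping '", cmp, "' (", stype,
                  "): a group has fewer than 3 samples", call. = FALSE)
          next
        }
        res <- run_two_sample_test(a, b, gate_alpha)
        rows[[cmp]] <- data.frame(
          annotation = ann, sample_type = stype, comparison = cmp,
          n1 = length(a), n2 = length(b), test = res$test,
          statistic = res$statistic, raw_p = res$p_value,
          stringsAsFactors = FALSE)
      }
      if (length(rows)) {
        fam <- do.call(rbind, rows)
        k <- family_size %||% nrow(fam)
        fam$adjusted_p <- pmin(1, fam$raw_p * k)
        out[[paste(ann, stype)]] <- fam
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
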