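#' Cohort summary table
#'
#' Summarizes participant attributes per cohort group (female students, male
#' students, male laborers): counts and percentages for categorical
#' attributes, mean and standard deviation for numeric ones. Percentages are
#' `100 * count / group size`, reported both raw and rounded.
#'
#' @param metadata a data frame with at least `occupation` and `gender`
#'   columns plus the requested attributes (one row per participant).
#' @param attributes character vector of metadata column names to summarize.
#' @param digits rounding for the displayed percentages (default 0, i.e.
#'   whole percent).
#' @return A data frame with columns `group`, `attribute`, `level`, `n`,
#'   `percent`, `percent_rounded` for categorical attributes and `group`,
#'   `attribute`, `mean`, `sd` for numeric ones (as attribute
#'   `"numeric_summary"`); group sizes are attached as an attribute.
#' @export
cohort_summary <- function(metadata, attributes = c("smoking", "drinking"),
                           digits = 0) {
  metadata <- as.data.frame(metadata)
  for (col in c("occupation", "gender"))
    if (is.null(metadata[[col]]))
      stop2("metadata lacks column '", col, "'")
  missing_attr <- setdiff(attributes, names(metadata))
  if (length(missing_attr))
    stop2("unknown attribute(s): ", paste(missing_attr, collapse = ", "))
  grp <- paste0(ifelse(metadata$gender == "F", "F", "M"),
                ifelse(metadata$occupation == "student", "St", "La"))
  grp <- factor(grp, levels = intersect(c("FSt", "MSt", "MLa", "FLa"),
                                        unique(grp)))
  sizes <- table(grp)
  rows <- list()
  for (attr_name in attributes) {
    v <- metadata[[attr_name]]
    if (is.numeric(v)) {
      agg_mean <- tapply(v, grp, mean)
      agg_sd <- tapply(v, grp, sd)
      rows[[attr_name]] <- data.frame(
        group = names(agg_mean), attribute = attr_name,
        level = NA_character_, n = NA_integer_, percent = NA_real_,
        percent_rounded = NA_real_,
        mean = as.numeric(agg_mean), sd = as.numeric(agg_sd),
        stringsAsFactors = FALSE)
    } else {
      v <- factor(v)
      tab <- table(grp, v)
      for (g in rownames(tab)) for (lv in colnames(tab)) {
        pct <- if (sizes[[g]] > 0) 100 * tab[g, lv] / sizes[[g]] else 0
        rows[[paste(attr_name, g, lv)]] <- data.frame(
          group = g, attribute = attr_name, level = lv,
          n = as.integer(tab[g, lv]), percent = pct,
          percent_rounded = round(pct, digits),
          mean = NA_real_, sd = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group_sizes") <- sizes
  out
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop2("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full occupation-analysis pipeline
#'
#' Orchestrates the stages in order: undetermined-feature removal, relative
#' abundance, alpha-diversity comparisons, Hellinger distances with PCoA and
#' ANOSIM (laborers vs. male students), per-feature differential abundance,
#' the LDA effect-size screen, and the recursive-elimination classifier.
#' All stage outputs are written under `out_dir` as TSV/JSON together with a
#' machine-readable `report.json` and a run log recording versions, seeds
#' and parameters. Reruns with the same configuration produce an identical
#' report.
#'
#' @param config a named list with entries: `table` (a [feature_table()]) and
#'   `metadata` (data frame), or `table_path`/`metadata_path` pointing at
#'   TSV files; `seed` (mandatory); `out_dir`; and optionally
#'   `min_prevalence` (10), `gate_alpha` (0.05), `lda_threshold` (4),
#'   `n_permutations` (999), `n_forests` (100), `n_trees` (500),
#'   `train_fraction` (0.7), `run_classifier` (TRUE).
#' @return Invisibly, a list with the per-stage results, the report list and
#'   the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed))
    stop2("validation error: 'seed' is mandatory in the pipeline config")
  out_dir <- config$out_dir %||% stop2("validation error: 'out_dir' missing")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  min_prev <- config$min_prevalence %||% 10L
  gate_alpha <- config$gate_alpha %||% 0.05
  lda_threshold <- config$lda_threshold %||% 4
  n_perm <- config$n_permutations %||% 999L
  n_forests <- config$n_forests %||% 100L
  n_trees <- config$n_trees %||% 500L
  train_fraction <- config$train_fraction %||% 0.7
  if (gate_alpha <= 0 || gate_alpha >= 1)
    stop2("validation error: 'gate_alpha' outside (0, 1)")

  loaded <- stage("load", {
    if (!is.null(config$table)) {
      list(table = config$table, metadata = validate_metadata(config$metadata))
    } else {
      load_feature_table(config$table_path, config$metadata_path)
    }
  })
  tab <- stage("drop_undetermined", drop_undetermined(loaded$table))
  metadata <- loaded$metadata
  seeds <- derive_seeds(config$seed, 4L)

  alpha_res <- stage("alpha_diversity",
                     suppressWarnings(compare_alpha_across_groups(
                       tab, metadata, gate_alpha = gate_alpha)))

  meta <- metadata[match(sample_ids(tab), metadata$sample_id), , drop = FALSE]
  male <- meta$gender == "M"
  beta_res <- list()
  diff_res <- list()
  lefse_res <- list()
  for (stype in unique(meta$sample_type)) {
    sel <- male & meta$sample_type == stype
    if (sum(sel) < 4L) next
    comp <- stage("relative_abundance",
                  relative_abundance(tab$counts[, sel, drop = FALSE]))
    grp <- factor(meta$occupation[sel], levels = c("student", "laborer"))
    if (nlevels(droplevels(grp)) < 2L || any(table(grp) < 3L)) next
    d <- stage("beta_diversity", hellinger_dist(comp))
    ord <- stage("pcoa", pcoa(d, n_axes = min(2L, sum(sel) - 1L)))
    an <- stage("anosim", anosim(d, as.character(grp),
                                 n_permutations = n_perm, seed = seeds[1L]))
    beta_res[[stype]] <- list(pcoa = ord, anosim = an)
    diff_res[[stype]] <- stage("diff_abundance",
                               per_feature_tests(comp, grp, gate_alpha))
    lefse_res[[stype]] <- stage("lefse",
                                lefse_two_class(comp, grp,
                                                alpha = gate_alpha,
                                                lda_threshold = lda_threshold,
                                                seed = seeds[2L]))
    write.table(diff_res[[stype]],
                file.path(out_dir, paste0("diffabund_", stype, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(lefse_res[[stype]],
                file.path(out_dir, paste0("lefse_", stype, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = rownames(ord$coordinates),
                           ord$coordinates),
                file.path(out_dir, paste0("pcoa_", stype, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(alpha_res, file.path(out_dir, "alpha_diversity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  classifier <- NULL
  if (config$run_classifier %||% TRUE) {
    classifier <- list()
    for (stype in names(beta_res)) {
      classifier[[stype]] <- stage("classifier",
        build_occupation_model(tab, metadata, sample_type = stype,
                               min_prevalence = min_prev,
                               train_fraction = train_fraction,
                               n_forests = n_forests, n_trees = n_trees,
                               seed = seeds[3L]))
    }
  }

  report <- list(
    package = "occubiome",
    version = as.character(packageVersion("occubiome")),
    parameters = list(seed = config$seed, min_prevalence = min_prev,
                      gate_alpha = gate_alpha, lda_threshold = lda_threshold,
                      n_permutations = n_perm, n_forests = n_forests,
                      n_trees = n_trees, train_fraction = train_fraction),
    n_samples = ncol(tab$counts),
    n_features = nrow(tab$counts),
    alpha = alpha_res,
    anosim = lapply(beta_res, function(b)
      list(R = b$anosim$statistic, p_value = b$anosim$p_value,
           n_permutations = b$anosim$n_permutations)),
    lefse_flagged = lapply(lefse_res, function(l) l$feature[l$pass]),
    classifier = if (!is.null(classifier)) lapply(classifier, function(f)
      list(features = f$model$features,
           train_accuracy = f$model$train_accuracy,
           test_accuracy = f$model$test_accuracy,
           n_features_screened = length(f$features_used)))
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    paste("occubiome version:", as.character(packageVersion("occubiome"))),
    paste("R version:", R.version.string),
    paste("master seed:", config$seed),
    paste("stage seeds (anosim, lefse, classifier):",
          paste(seeds[1:3], collapse = ", ")),
    paste("parameters: min_prevalence =", min_prev,
          "| gate_alpha =", gate_alpha, "| lda_threshold =", lda_threshold,
          "| n_permutations =", n_perm, "| n_forests =", n_forests,
          "| n_trees =", n_trees)), log_path)

  invisible(list(alpha = alpha_res, beta = beta_res, diffabund = diff_res,
                 lefse = lefse_res, classifier = classifier,
                 report = report, report_path = report_path,
                 out_dir = out_dir))
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the report produced by [run_pipeline()] for the required fields
#' and types declared in the JSON schema shipped under
#' `inst/schema/report.schema.json`.
#'
#' @param report a report list or the path to a `report.json`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(
    system.file("schema", "report.schema.json", package = "occubiome"))
  required <- unlist(schema$required)
  missing <- setdiff(required, names(report))
  if (length(missing))
    stop2("report lacks required field(s): ", paste(missing, collapse = ", "))
  for (fld in c("seed", "min_prevalence", "gate_alpha")) {
    if (!is.numeric(report$parameters[[fld]] %||% NA))
      stop2("report parameter '", fld, "' must be numeric")
  }
  if (!is.numeric(report$n_samples) || !is.numeric(report$n_features))
    stop2("'n_samples' and 'n_features' must be numeric")
  invisible(TRUE)
}
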