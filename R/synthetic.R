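#' Configuration for a synthetic two-occupation study
#'
#' Defines the ground-truth parameters of a simulated cohort: two occupation
#' groups of equal size, a sparse compositional feature pool with a chosen
#' number of group-informative features, per-sample sequencing depths, and
#' binary lifestyle covariates.
#'
#' The defaults emulate the male modeling cohort of a saliva/feces
#' metagenomic occupation study: 20 students and 20 laborers, a pool of 200
#' moderately prevalent features of which 5 differ between occupations at an
#' 8-fold change, uneven baseline composition (symmetric Dirichlet with
#' concentration 0.5), 30% structural absence per feature and sample, and
#' negative-binomial read depths around 50,000. Smoking and drinking rates
#' follow the cohort pattern (students smoke less, both groups mostly drink).
#'
#' @param n_per_group samples per occupation group.
#' @param n_features number of features in the pool.
#' @param n_informative number of group-informative features
#'   (`<= n_features`).
#' @param effect_size multiplicative fold-change applied to informative
#'   features' base abundances in the laborer group (direction per feature is
#'   drawn at random); must be positive.
#' @param depth_mean,depth_dispersion mean and dispersion (negative-binomial
#'   `size`) of per-sample total read counts; `depth_dispersion = Inf` gives
#'   a fixed depth.
#' @param base_concentration symmetric Dirichlet concentration of the base
#'   composition; small values give uneven communities.
#' @param sparsity probability in `[0, 1)` that a feature is structurally
#'   absent from a given sample.
#' @param covariate_rates named list with per-group probabilities for the
#'   `smoking`, `drinking` and `female` flags; each a numeric vector with
#'   elements `student` and `laborer`.
#' @param sample_type `"saliva"` or `"feces"`.
#' @param seed integer seed making the whole study reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 20,
                              n_features = 200,
                              n_informative = 5,
                              effect_size = 8,
                              depth_mean = 5e4,
                              depth_dispersion = 10,
                              base_concentration = 0.5,
                              sparsity = 0.3,
                              covariate_rates = list(
                                smoking = c(student = 0.20, laborer = 0.65),
                                drinking = c(student = 0.80, laborer = 0.75),
                                female = c(student = 0, laborer = 0)),
                              sample_type = c("saliva", "feces"),
                              seed = 1L) {
  sample_type <- match.arg(sample_type)
  if (n_per_group < 1 || n_features < 1)
    stop2("'n_per_group' and 'n_features' must be positive")
  if (n_informative < 0 || n_informative > n_features)
    stop2("'n_informative' must lie in [0, n_features]")
  if (effect_size <= 0) stop2("'effect_size' must be positive")
  if (depth_mean <= 0) stop2("'depth_mean' must be positive")
  if (depth_dispersion <= 0) stop2("'depth_dispersion' must be positive")
  if (base_concentration <= 0) stop2("'base_concentration' must be positive")
  if (sparsity < 0 || sparsity >= 1) stop2("'sparsity' must lie in [0, 1)")
  for (nm in c("smoking", "drinking", "female")) {
    r <- covariate_rates[[nm]]
    if (is.null(r) || !all(c("student", "laborer") %in% names(r)) ||
        any(r < 0) || any(r > 1))
      stop2("covariate_rates$", nm,
            " must give probabilities for 'student' and 'laborer'")
  }
  if (is.null(seed)) stop2("'seed' is mandatory")
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         effect_size = effect_size,
         depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         base_concentration = base_concentration,
         sparsity = sparsity,
         covariate_rates = covariate_rates,
         sample_type = sample_type,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @return `path` (writer) or a `simulation_config` (reader).
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  out <- unclass(config)
  # yaml drops names of atomic vectors; store the rates as maps
  out$covariate_rates <- lapply(out$covariate_rates, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$covariate_rates <- lapply(raw$covariate_rates, unlist)
  do.call(simulation_config, raw)
}

#' Simulate a seven-rank taxonomy
#'
#' Builds a rooted taxonomy in which every species carries a complete
#' Kingdom-to-Species lineage. Higher ranks are obtained by randomly
#' coalescing the rank below, and kingdoms are drawn with probabilities
#' mimicking a bacteria-dominated community with some archaea and few
#' viruses.
#'
#' @param n_species number of species (>= 1).
#' @param seed integer seed; the tree is deterministic given the seed.
#' @return A data frame with columns `Kingdom` ... `Species`, one row per
#'   species.
#' @export
simulate_taxonomy <- function(n_species, seed = 1L) {
  if (!is.numeric(n_species) || n_species < 1)
    stop2("'n_species' must be >= 1")
  n_species <- as.integer(n_species)
  with_seed(seed, {
    n_genus <- max(1L, ceiling(n_species / 3))
    n_family <- max(1L, ceiling(n_genus / 2))
    n_order <- max(1L, ceiling(n_family / 2))
    n_class <- max(1L, ceiling(n_order / 2))
    n_phylum <- max(1L, ceiling(n_class / 2))
    lab <- function(prefix, n) sprintf("%s__%04d", prefix, seq_len(n))
    genus <- sample(lab("g", n_genus), n_species, replace = TRUE)
    g2f <- sample(lab("f", n_family), n_genus, replace = TRUE)
    f2o <- sample(lab("o", n_order), n_family, replace = TRUE)
    o2c <- sample(lab("c", n_class), n_order, replace = TRUE)
    c2p <- sample(lab("p", n_phylum), n_class, replace = TRUE)
    p2k <- sample(c("Bacteria", "Archaea", "Viruses"), n_phylum,
                  replace = TRUE, prob = c(0.85, 0.14, 0.01))
    fam <- g2f[match(genus, lab("g", n_genus))]
    ord <- f2o[match(fam, lab("f", n_family))]
    cls <- o2c[match(ord, lab("o", n_order))]
    phy <- c2p[match(cls, lab("c", n_class))]
    kng <- p2k[match(phy, lab("p", n_phylum))]
    data.frame(Kingdom = kng, Phylum = phy, Class = cls, Order = ord,
               Family = fam, Genus = genus,
               Species = sprintf("s__%04d", seq_len(n_species)),
               stringsAsFactors = FALSE)
  })
}

# Symmetric Dirichlet draw via normalized gammas.
rdirichlet_sym <- function(n_parts, concentration) {
  g <- rgamma(n_parts, shape = concentration, rate = 1)
  if (sum(g) == 0) g <- rep(1, n_parts)
  g / sum(g)
}

#' Simulate a two-occupation metagenomic study
#'
#' Generates a feature-count table, sample metadata and the generating ground
#' truth under a Dirichlet-multinomial model with structural zeros:
#' a base composition is drawn from a symmetric Dirichlet; the informative
#' features' proportions are multiplied by the effect size (direction drawn
#' per feature) in the laborer group and renormalized; each feature is
#' structurally absent from a sample with probability `sparsity`; per-sample
#' depths follow a negative binomial; counts are drawn multinomially at that
#' depth. Everything is reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A list of class `synthetic_study` with elements `table`
#'   (a [feature_table()] with lineage), `metadata` (data frame), `truth`
#'   (list with `informative`, `direction`, and the group compositions) and
#'   `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    m <- config$n_features
    n_g <- config$n_per_group
    n <- 2L * n_g
    taxonomy <- simulate_taxonomy(m, seed = derive_seeds(config$seed, 1L))
    features <- taxonomy$Species

    base <- rdirichlet_sym(m, config$base_concentration)
    informative <- sort(sample(features, config$n_informative))
    direction <- setNames(
      sample(c("up", "down"), config$n_informative, replace = TRUE),
      informative)
    lab_prop <- base
    idx <- match(informative, features)
    fold <- ifelse(direction == "up", config$effect_size,
                   1 / config$effect_size)
    lab_prop[idx] <- lab_prop[idx] * fold
    lab_prop <- lab_prop / sum(lab_prop)

    occupation <- rep(c("student", "laborer"), each = n_g)
    props <- cbind(matrix(base, m, n_g), matrix(lab_prop, m, n_g))

    # structural zeros, then renormalize each sample
    absent <- matrix(rbinom(m * n, 1L, config$sparsity) == 1L, m, n)
    props[absent] <- 0
    for (j in seq_len(n)) {
      if (all(props[, j] == 0)) # degenerate mask: keep the dominant feature
        props[which.max(base), j] <- 1
      props[, j] <- props[, j] / sum(props[, j])
    }

    depth <- if (is.finite(config$depth_dispersion)) {
      pmax(1L, rnbinom(n, size = config$depth_dispersion,
                       mu = config$depth_mean))
    } else rep(as.integer(round(config$depth_mean)), n)

    counts <- matrix(0L, m, n)
    for (j in seq_len(n))
      counts[, j] <- rmultinom(1L, depth[j], props[, j])[, 1L]

    gender <- ifelse(
      runif(n) < config$covariate_rates$female[occupation], "F", "M")
    smoking <- ifelse(
      runif(n) < config$covariate_rates$smoking[occupation], "yes", "no")
    drinking <- ifelse(
      runif(n) < config$covariate_rates$drinking[occupation], "yes", "no")
    type_letter <- if (config$sample_type == "saliva") "S" else "F"
    sample_id <- sprintf("%s%s%02d%s",
                         ifelse(gender == "F", "F", "M"),
                         ifelse(occupation == "student", "St", "La"),
                         ave(seq_len(n), occupation, FUN = seq_along),
                         type_letter)
    dimnames(counts) <- list(features, sample_id)

    metadata <- data.frame(
      sample_id = sample_id, occupation = occupation, gender = gender,
      sample_type = config$sample_type, smoking = smoking,
      drinking = drinking, stringsAsFactors = FALSE)

    structure(
      list(table = feature_table(counts, kind = "taxon@Species",
                                 lineage = taxonomy),
           metadata = metadata,
           truth = list(informative = informative, direction = direction,
                        base_composition = setNames(base, features),
                        laborer_composition = setNames(lab_prop, features),
                        depth = setNames(depth, sample_id)),
           config = config),
      class = "synthetic_study")
  })
}

#' Precision/recall of a selected feature set against the planted truth
#'
#' @param selected character vector of selected feature ids (may be empty).
#' @param truth the `truth` element of a [simulate_study()] result, or any
#'   list with an `informative` character vector.
#' @return A list with `n_selected`, `n_informative`, `n_recovered`,
#'   `precision` and `recall` (both in `[0, 1]`; precision is 0 when nothing
#'   was selected).
#' @export
ground_truth_recovery <- function(selected, truth) {
  informative <- if (is.list(truth)) truth$informative else truth
  if (length(informative) == 0L)
    stop2("'truth' carries no informative features")
  hits <- intersect(selected, informative)
  list(n_selected = length(selected),
       n_informative = length(informative),
       n_recovered = length(hits),
       precision = if (length(selected)) length(hits) / length(selected) else 0,
       recall = length(hits) / length(informative))
}
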