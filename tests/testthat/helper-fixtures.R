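# Small deterministic fixtures used across the suite.

toy_counts <- function() {
  matrix(c(4L, 0L, 2L,
           6L, 3L, 0L,
           0L, 5L, 1L,
           2L, 2L, 2L),
         nrow = 3L,
         dimnames = list(c("fA", "fB", "fC"),
                         c("s1", "s2", "s3", "s4")))
}

toy_table <- function() feature_table(toy_counts(), kind = "KEGG-pathway")

toy_metadata <- function(ids = c("s1", "s2", "s3", "s4")) {
  data.frame(sample_id = ids,
             occupation = c("student", "student", "laborer", "laborer"),
             gender = "M",
             sample_type = "saliva",
             smoking = c("no", "no", "yes", "yes"),
             drinking = c("yes", "no", "yes", "no"),
             stringsAsFactors = FALSE)
}

# random composition over m features (never exactly zero-sum)
random_composition <- function(m) {
  p <- runif(m)
  p / sum(p)
}

small_null_config <- function(seed, n_per_group = 10, n_features = 40) {
  simulation_config(n_per_group = n_per_group, n_features = n_features,
                    n_informative = 5, effect_size = 1,
                    depth_mean = 2000, depth_dispersion = 10,
                    sparsity = 0.2, seed = seed)
}
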