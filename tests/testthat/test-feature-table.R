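test_that("constructor validates counts and identifiers", {
  m <- toy_counts()
  expect_s3_class(feature_table(m), "feature_table")

  bad <- m
  bad[2, 3] <- -1L
  expect_error(feature_table(bad), "negative count.*fB.*s3")

  dup <- m
  rownames(dup) <- c("fA", "fA", "fC")
  expect_error(feature_table(dup), "duplicated feature ids")

  frac <- m * 1.0
  frac[1, 1] <- 0.5
  expect_error(feature_table(frac), "whole numbers")
})

test_that("TSV round-trip preserves the table and metadata mismatches are named", {
  tab <- toy_table()
  tp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, tp)
  write_sample_metadata(toy_metadata(), mp)

  loaded <- load_feature_table(tp, mp, kind = "KEGG-pathway")
  expect_equal(loaded$table$counts, tab$counts, ignore_attr = FALSE)
  expect_identical(loaded$metadata$sample_id, colnames(tab$counts))

  # metadata lacking one sample must name it
  meta_short <- toy_metadata()[-3, ]
  write_sample_metadata(meta_short, mp)
  expect_error(load_feature_table(tp, mp), "s3")
})

test_that("undetermined features are removed by id or lineage", {
  m <- toy_counts()
  rownames(m) <- c("A", "uncultured_X", "B")
  tab <- feature_table(m)
  out <- drop_undetermined(tab)
  expect_identical(rownames(out$counts), c("A", "B"))
  expect_identical(out$counts, m[c("A", "B"), ])

  # no matching features: identity
  tab2 <- toy_table()
  expect_identical(drop_undetermined(tab2)$counts, tab2$counts)

  # everything matches: error
  rownames(m) <- c("unassigned_1", "Unassigned_2", "UNCULTURED_Y")
  expect_error(drop_undetermined(feature_table(m)), "all features")
})

test_that("relative abundance is the per-sample proportion and flags empty samples", {
  m <- matrix(c(2L, 2L, 9L, 1L), 2,
              dimnames = list(c("f1", "f2"), c("a", "b")))
  ra <- relative_abundance(feature_table(m))
  expect_equal(ra[, "a"], c(f1 = 0.5, f2 = 0.5))
  expect_equal(ra[, "b"], c(f1 = 0.9, f2 = 0.1))

  m0 <- cbind(m, c(0L, 0L))
  colnames(m0)[3] <- "empty"
  expect_error(relative_abundance(feature_table(m0)), "empty")
})

test_that("composition columns sum to one after count-preserving operations", {
  set.seed(11)
  m <- matrix(rpois(300, 4), 30,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:10)))
  rownames(m)[7] <- "uncultured_sp"
  tab <- feature_table(m)
  for (op in list(function(t) drop_undetermined(t),
                  function(t) prevalence_filter(t, 3))) {
    ra <- relative_abundance(op(tab))
    expect_true(all(abs(colSums(ra) - 1) < 1e-9))
  }
})

test_that("prevalence filter keeps features detected in enough samples", {
  m <- matrix(c(5L, 0L, 0L,
                1L, 2L, 0L,
                3L, 3L, 3L), nrow = 3, byrow = TRUE,
              dimnames = list(c("once", "twice", "thrice"),
                              c("s1", "s2", "s3")))
  tab <- feature_table(m)
  expect_identical(prevalence_filter(tab, 0)$counts, tab$counts)
  expect_identical(rownames(prevalence_filter(tab, 2)$counts),
                   c("twice", "thrice"))
  expect_error(prevalence_filter(tab, 4), "min_samples")

  # idempotence
  once <- prevalence_filter(tab, 2)
  expect_identical(prevalence_filter(once, 2)$counts, once$counts)
})

test_that("taxonomic aggregation conserves per-sample totals", {
  tax <- simulate_taxonomy(20, seed = 3)
  set.seed(5)
  m <- matrix(rpois(20 * 6, 10), 20,
              dimnames = list(tax$Species, sprintf("s%d", 1:6)))
  tab <- feature_table(m, lineage = tax)

  for (rank in c("Genus", "Phylum", "Kingdom")) {
    agg <- aggregate_taxonomy(tab, tax, rank)
    expect_identical(colSums(agg$counts), colSums(m))
    expect_identical(sort(rownames(agg$counts)), sort(unique(tax[[rank]])))
  }

  # two species of one genus sum their counts
  g <- tax$Genus[1]
  sp <- tax$Species[tax$Genus == g]
  agg <- aggregate_taxonomy(tab, tax, "Genus")
  expect_equal(agg$counts[g, ], colSums(m[sp, , drop = FALSE]))

  # species-level aggregation is the identity
  expect_identical(aggregate_taxonomy(tab, tax, "Species")$counts, tab$counts)

  # unknown species are listed
  rownames(m)[1] <- "s__unknown"
  expect_error(aggregate_taxonomy(feature_table(m), tax, "Genus"),
               "s__unknown")
})

test_that("group codes combine gender, occupation and sample type", {
  meta <- toy_metadata()
  meta$gender <- c("F", "M", "M", "F")
  meta$sample_type <- c("saliva", "feces", "saliva", "feces")
  expect_identical(group_code(meta), c("FStS", "MStF", "MLaS", "FLaF"))
})
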