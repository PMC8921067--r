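test_that("reference databases have the promised structure and divergence", {
  db <- generate_reference_database(10, 3, seed = 1)
  expect_equal(nrow(db$strains), 30)
  expect_equal(nrow(db$genomes), 30)
  expect_equal(length(unique(db$strains$species)), 10)
  expect_false(anyDuplicated(db$strains$strain_id) > 0)
  expect_true(all(db$strains$copy_number >= 1 & db$strains$copy_number <= 15))
  # copy numbers are species-level traits shared by strains
  per_species <- tapply(db$strains$copy_number, db$strains$species,
                        function(x) length(unique(x)))
  expect_true(all(per_species == 1))
  # within species: 1-5 substitutions between strain pairs is <= 10 diffs
  split_seq <- function(s) strsplit(s, "")[[1]]
  sp <- split(db$strains$strain_id, db$strains$species)
  for (ids in sp) {
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j) {
        d <- sum(split_seq(db$sequences[ids[i]]) != split_seq(db$sequences[ids[j]]))
        expect_lte(d, 10)
        expect_gte(d, 1)
      }
    }
  }
})

test_that("two single-strain species diverge below 97% identity", {
  db <- generate_reference_database(2, 1, seed = 7)
  ident <- pairwise_identity(db$sequences[[1]], db$sequences[[2]])
  expect_lte(ident, 0.97)
})

test_that("generation is deterministic given the seed", {
  a <- generate_reference_database(4, 2, seed = 99)
  b <- generate_reference_database(4, 2, seed = 99)
  expect_identical(a, b)
  c <- generate_reference_database(4, 2, seed = 100)
  expect_false(identical(a$sequences, c$sequences))

  bp1 <- generate_phenotype_matrix(a, prevalence = 0.4, coherence = 0.8,
                                   seed = 3)
  bp2 <- generate_phenotype_matrix(a, prevalence = 0.4, coherence = 0.8,
                                   seed = 3)
  expect_identical(bp1, bp2)

  cfg <- effect_config(conditions = c("control", "butyrate"), depth = 5000,
                       seed = 42)
  e1 <- simulate_experiment(a, cfg)
  e2 <- simulate_experiment(a, cfg)
  expect_identical(e1$counts$mat, e2$counts$mat)
  expect_identical(e1$truth$true_props, e2$truth$true_props)
})

test_that("generator rejects degenerate arguments", {
  expect_error(generate_reference_database(1, 3, seed = 1), "n_species")
  expect_error(generate_reference_database(5, 0, seed = 1), "strains_per_species")
  expect_error(effect_config(replicates = 1), "replicates")
  expect_error(effect_config(depth = 10), "depth")
  expect_error(effect_config(multiplier_bounds = c(-1, 2)), "multiplier_bounds")
  expect_error(generate_phenotype_matrix(fix_ref_db(), prevalence = 1.5),
               "prevalence")
})

test_that("phenotype matrix respects prevalence and coherence", {
  db <- generate_reference_database(6, 3, seed = 2)
  # coherence 1: all genomes of a species share one state per phenotype
  b1 <- generate_phenotype_matrix(db, c("butyrate", "B12"), prevalence = 0.5,
                                  coherence = 1, seed = 5)
  states <- tapply(seq_len(nrow(b1$mat)), b1$lineage$species, function(idx) {
    apply(b1$mat[idx, , drop = FALSE], 2, function(x) length(unique(x)))
  })
  expect_true(all(unlist(states) == 1))
  # prevalence 1 + coherence 1: all-ones columns
  b2 <- generate_phenotype_matrix(db, "butyrate", prevalence = 1,
                                  coherence = 1, seed = 5)
  expect_true(all(b2$mat == 1))
})

test_that("genome flip fraction matches 1 - coherence at scale", {
  # 10,000 genome x phenotype Bernoulli events at coherence 0.9
  db <- generate_reference_database(200, 5, seed = 3)
  b <- generate_phenotype_matrix(db, paste0("ph", 1:10), prevalence = 0.5,
                                 coherence = 0.9, seed = 3)
  majority <- apply(b$mat, 2, function(col) {
    per_sp <- tapply(col, b$lineage$species, function(x) {
      as.integer(mean(x) >= 0.5)
    })
    per_sp[b$lineage$species]
  })
  flip_frac <- mean(b$mat != majority)
  # majority-vote recovery slightly underestimates flips; wide +/- 0.05 band
  expect_lt(abs(flip_frac - 0.1), 0.05)
})

test_that("simulated counts conserve depth and the null model is flat", {
  db <- generate_reference_database(8, 2, seed = 4)
  cfg <- effect_config(depth = 2000, seed = 9)
  ex <- simulate_experiment(db, cfg)
  expect_true(all(colSums(ex$counts$mat) == cfg$depth))
  expect_true(all(ex$truth$multipliers["control", ] == 1))
  expect_equal(colSums(ex$truth$true_props), rep(1, ncol(ex$truth$true_props)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # no effects, no overdispersion, large depth: conditions nearly identical
  cfg0 <- effect_config(conditions = c("control", "acetate", "butyrate"),
                        affected_fraction = 0, overdispersion = 0,
                        depth = 200000, seed = 10)
  ex0 <- simulate_experiment(db, cfg0)
  rel <- to_relative(ex0$counts)
  by_cond <- sapply(unique(rel$meta$condition), function(cond) {
    rowMeans(rel$mat[, rel$meta$condition == cond, drop = FALSE])
  })
  expect_lt(max(abs(by_cond - by_cond[, 1])), 0.01)
})

test_that("a planted tenfold effect shows a 5-20x mean abundance ratio", {
  # Monte-Carlo over 20 seeds, one planted strain per condition
  ratios <- vapply(1:20, function(s) {
    db <- generate_reference_database(10, 3, seed = 400 + s)
    n <- nrow(db$strains)
    cfg <- effect_config(conditions = c("control", "butyrate"),
                         affected_fraction = 1 / n,
                         multiplier_bounds = c(10, 10),
                         depth = 100000, seed = 500 + s)
    ex <- simulate_experiment(db, cfg)
    planted <- colnames(ex$truth$multipliers)[ex$truth$multipliers["butyrate", ] != 1]
    rel <- to_relative(ex$counts)
    ctrl <- rowMeans(rel$mat[, rel$meta$condition == "control", drop = FALSE])
    trt <- rowMeans(rel$mat[, rel$meta$condition == "butyrate", drop = FALSE])
    trt[planted] / ctrl[planted]
  }, numeric(1))
  expect_gte(mean(ratios), 5)
  expect_lte(mean(ratios), 20)
})

test_that("ground-truth CPI equals abundance-weighted genome bits", {
  db <- generate_reference_database(5, 2, seed = 6)
  b <- generate_phenotype_matrix(db, c("butyrate", "B2"), prevalence = 0.5,
                                 coherence = 0.9, seed = 7)
  cfg <- effect_config(conditions = c("control", "acetate"), depth = 5000,
                       seed = 8)
  ex <- simulate_experiment(db, cfg, bpm = b)
  bits <- b$mat[paste0("G_", rownames(ex$truth$true_props)), ]
  manual <- 100 * t(ex$truth$true_props) %*% bits
  expect_equal(unclass(ex$truth$cpi), unclass(manual), tolerance = 1e-12)
  expect_true(all(ex$truth$cpi >= 0 & ex$truth$cpi <= 100))
})
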