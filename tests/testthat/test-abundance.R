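test_that("relative conversion closes samples and flags empty ones", {
  meta <- fix_meta()
  mat <- matrix(c(10, 30, 0, 0, 1, 0, 25, 25, 50, 2, 3, 5), nrow = 3,
                dimnames = list(c("a", "b", "c"), meta$sample_id))
  tab <- abund_table(mat, meta = meta)
  rel <- to_relative(tab)
  expect_equal(unname(rel$mat[, 1]), c(0.25, 0.75, 0))
  expect_equal(colSums(rel$mat), setNames(rep(1, 4), meta$sample_id))
  expect_equal(rel$mode, "relative")

  single <- abund_table(matrix(7, 1, 1, dimnames = list("a", "s")))
  expect_equal(unname(to_relative(single)$mat[1, 1]), 1.0)

  mat[, 2] <- 0
  expect_error(to_relative(abund_table(mat)), "control_2")
})

test_that("abund_table validates closure and negativity", {
  m <- matrix(c(0.6, 0.5), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(abund_table(m, mode = "relative"), "not summing to 1")
  expect_error(abund_table(matrix(-1, 1, 1, dimnames = list("a", "s"))),
               "non-negative")
})

test_that("copy-number renormalization reweights and re-closes", {
  cn <- cn_table(data.frame(rank = "species", name = c("spA", "spB"),
                            mean_copies = c(2, 4)))
  tab <- abund_table(matrix(c(0.5, 0.5), 2, 1,
                            dimnames = list(c("spA", "spB"), "s1")),
                     mode = "relative")
  out <- copy_number_renormalize(tab, cn)
  expect_equal(unname(out$mat[, 1]), c(2 / 3, 1 / 3))

  # equal copy numbers leave the table unchanged; so does scaling all copies
  cn_eq <- cn_table(data.frame(rank = "species", name = c("spA", "spB"),
                               mean_copies = c(3, 3)))
  expect_equal(copy_number_renormalize(tab, cn_eq)$mat, tab$mat)
  cn_x10 <- cn_table(data.frame(rank = "species", name = c("spA", "spB"),
                                mean_copies = c(20, 40)))
  expect_equal(copy_number_renormalize(tab, cn_x10)$mat, out$mat)

  # single taxon stays 1 regardless
  one <- abund_table(matrix(1, 1, 1, dimnames = list("spA", "s1")),
                     mode = "relative")
  expect_equal(unname(copy_number_renormalize(one, cn)$mat[1, 1]), 1.0)
})

test_that("missing copy numbers fall back to the grand mean or error", {
  cn <- cn_table(data.frame(rank = "species", name = "spA", mean_copies = 2))
  tab <- abund_table(matrix(c(0.5, 0.5), 2, 1,
                            dimnames = list(c("spA", "spX"), "s1")),
                     mode = "relative")
  out <- copy_number_renormalize(tab, cn, fallback = TRUE)
  expect_equal(attr(out, "fallback_taxa"), "spX")
  expect_equal(unname(out$mat[, 1]), c(0.5, 0.5))  # grand mean = 2 = spA
  expect_error(copy_number_renormalize(tab, cn, fallback = FALSE), "spX")

  # multi-name taxa average their constituents' copy numbers
  cn2 <- cn_table(data.frame(rank = "species", name = c("spA", "spB"),
                             mean_copies = c(2, 6)))
  tab2 <- abund_table(matrix(c(0.5, 0.5), 2, 1,
                             dimnames = list(c("spA/spB", "spA"), "s1")),
                      mode = "relative")
  out2 <- copy_number_renormalize(tab2, cn2)
  expect_equal(unname(out2$mat[, 1]), c((0.5 / 4), (0.5 / 2)) / (0.5 / 4 + 0.5 / 2))
})

test_that("rank aggregation sums strains and conserves totals", {
  db <- fix_ref_db()
  asn <- assign_taxonomy(db$sequences, db)
  meta <- fix_meta()
  mat <- matrix(c(0.2, 0.5, 0.3, 0.1, 0.6, 0.3, 0.25, 0.5, 0.25,
                  0.4, 0.2, 0.4), 3,
                dimnames = list(c("s1", "s2", "s3"), meta$sample_id))
  tab <- abund_table(mat, meta = meta, mode = "relative")
  agg <- aggregate_to_rank(tab, asn, rank = "species")
  expect_setequal(rownames(agg$mat), c("obeum", "wexlerae"))
  expect_equal(unname(agg$mat["obeum", 1]), 0.2 + 0.3)
  expect_equal(colSums(agg$mat), colSums(tab$mat))

  # all-distinct rank keeps values unchanged
  agg_strain <- aggregate_to_rank(tab, within(as.data.frame(asn), {
    species <- asv_id
  }), rank = "species")
  expect_equal(sort(rownames(agg_strain$mat)), sort(rownames(tab$mat)))

  asn_missing <- as.data.frame(asn)[-1, ]
  expect_error(aggregate_to_rank(tab, asn_missing, rank = "species"),
               "unassigned")
})

test_that("aggregation and renormalization commute at the same rank", {
  db <- fix_ref_db()
  asn <- assign_taxonomy(db$sequences, db)
  cn <- cn_table(data.frame(rank = "species", name = c("obeum", "wexlerae"),
                            mean_copies = c(2, 5)))
  meta <- fix_meta()
  set.seed(30)
  mat <- matrix(runif(12), 3, dimnames = list(c("s1", "s2", "s3"),
                                              meta$sample_id))
  mat <- sweep(mat, 2, colSums(mat), "/")
  tab <- abund_table(mat, meta = meta, mode = "relative")

  a_then_r <- copy_number_renormalize(aggregate_to_rank(tab, asn, "species"),
                                      cn, rank = "species")
  r_then_a <- aggregate_to_rank(
    copy_number_renormalize(tab, cn, rank = "species", assignments = asn),
    asn, "species")
  expect_equal(a_then_r$mat[rownames(r_then_a$mat), ], r_then_a$mat,
               tolerance = 1e-12)
})

test_that("observed taxon counting uses a strict detection threshold", {
  meta <- fix_meta()
  mat <- matrix(c(0.6, 0.3, 0.0), 3, 4,
                dimnames = list(c("a", "b", "c"), meta$sample_id))
  tab <- abund_table(mat, mode = "counts")
  expect_equal(count_observed(tab, threshold = 0), 2)
  expect_equal(count_observed(tab, threshold = 0.9), 0)
  expect_equal(count_observed(tab, samples = "control_1", threshold = 0), 2)
  expect_error(count_observed(tab, samples = character(0)), "empty")
  expect_error(count_observed(tab, threshold = -1), ">= 0")
})
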