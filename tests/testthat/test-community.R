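test_that("Shannon diversity matches hand values and vegan", {
  expect_equal(shannon_diversity(rep(0.25, 4)), log(4))
  expect_equal(shannon_diversity(c(1)), 0)
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_error(shannon_diversity(c(-0.1, 1.1)), "negative")

  # uniform composition maximizes H; cross-check against vegan
  set.seed(50)
  for (i in 1:10) {
    a <- rdirichlet_test(6)
    expect_lte(shannon_diversity(a), log(6) + 1e-12)
    expect_equal(shannon_diversity(a), unname(vegan::diversity(a)),
                 tolerance = 1e-12)
  }
})

test_that("Bray-Curtis follows 1 - sum(min) on closed compositions", {
  a <- c(t1 = 0.6, t2 = 0.4, t3 = 0)
  b <- c(t1 = 0.2, t2 = 0.4, t3 = 0.4)
  expect_equal(bray_curtis(a, b), 0.4)
  expect_equal(bray_curtis(a, a), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)  # disjoint supports
  expect_error(bray_curtis(a, b[c(2, 1, 3)]), "names")
  expect_error(bray_curtis(a, c(0.5, 0.5)), "index")

  # range and vegan agreement on random compositions
  set.seed(51)
  for (i in 1:10) {
    x <- rdirichlet_test(5); y <- rdirichlet_test(5)
    d <- bray_curtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, as.numeric(vegan::vegdist(rbind(x, y))),
                 tolerance = 1e-12)
  }
})

test_that("PCoA reproduces distances and reports negative eigenvalues", {
  # Euclidean-generated distances embed exactly
  set.seed(52)
  for (i in 1:5) {
    pts <- matrix(rnorm(5 * 3), 5, 3)
    d <- as.matrix(dist(pts))
    p <- pcoa(d)
    expect_equal(as.matrix(dist(p$coords)), d, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_true(all(p$eig > -1e-8))
  }

  # identical samples coincide
  d2 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(d2)
  expect_equal(unname(p2$coords[1, ]), unname(p2$coords[2, ]))

  # three equidistant samples: all embedded pairs equal
  d3 <- matrix(0.5, 3, 3); diag(d3) <- 0
  p3 <- pcoa(d3)
  pd <- dist(p3$coords)
  expect_equal(max(pd) - min(pd), 0, tolerance = 1e-9)

  # Bray-Curtis matrices can yield negative eigenvalues; they are reported
  set.seed(53)
  mat <- matrix(rgamma(8 * 12, 1), 8, 12,
                dimnames = list(paste0("t", 1:8), paste0("s", 1:12)))
  tab <- abund_table(mat)
  bc <- bray_curtis_matrix(tab)
  pbc <- pcoa(bc)
  expect_equal(length(pbc$eig), 12)  # one per sample (one ~0 from centering)
  expect_true(any(pbc$eig < 0))
  # cross-check eigenvalues against ape's independent implementation
  ap <- ape::pcoa(as.dist(bc))
  k <- sum(pbc$eig > 1e-8)
  expect_equal(pbc$eig[seq_len(k)], ap$values$Eigenvalues[seq_len(k)],
               tolerance = 1e-6)

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(asym), "symmetric")
})

test_that("exact Mann-Whitney matches hand enumeration and wilcox.test", {
  r <- mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 2 / 70)
  expect_equal(round(r$p.value, 2), 0.03)

  r2 <- mann_whitney_exact(c(1, 2, 3, 5), c(4, 6, 7, 8))
  expect_equal(unname(r2$statistic), 1)
  expect_equal(r2$p.value, 4 / 70)

  # identical groups: p = 1
  expect_equal(mann_whitney_exact(c(2, 2, 2), c(2, 2, 2))$p.value, 1)

  # tie-free data agree with stats::wilcox.test exact two-sided p
  set.seed(54)
  for (i in 1:25) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- sample(seq_len(50), na); y <- sample(setdiff(seq_len(50), x), nb)
    expect_equal(mann_whitney_exact(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }

  expect_error(mann_whitney_exact(1, c(1, 2)), "at least two")
})

test_that("tie-free p values live in [2/C(n,na), 1] with the floor at separation", {
  set.seed(55)
  for (i in 1:20) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    x <- sample(seq_len(100), na); y <- sample(setdiff(seq_len(100), x), nb)
    p <- mann_whitney_exact(x, y)$p.value
    floor_p <- 2 / choose(na + nb, na)
    expect_gte(p, floor_p - 1e-12)
    expect_lte(p, 1)
    separated <- max(x) < min(y) || max(y) < min(x)
    expect_equal(abs(p - floor_p) < 1e-12, separated)
  }
})

test_that("fold modulation classification follows the fivefold rule", {
  expect_equal(classify_modulation(0.01, 0.06)$direction, "increased")
  expect_equal(classify_modulation(0.02, 0.02)$direction, "unaltered")
  expect_equal(classify_modulation(0.05, 0.01)$direction, "unaltered") # 5x not >5x
  expect_equal(classify_modulation(0.05, 0.009)$direction, "decreased")

  # detection-limit cases: new and lost features
  new <- classify_modulation(0, 0.046)
  expect_equal(new$direction, "increased")
  expect_equal(new$marker, "new")
  lost <- classify_modulation(0.046, 0)
  expect_equal(lost$direction, "decreased")
  expect_equal(lost$marker, "lost")
  expect_equal(classify_modulation(0, 0)$direction, "unaltered")

  expect_error(classify_modulation(-1, 0.5), ">= 0")

  # anti-symmetry: swapping control and treatment flips the direction
  set.seed(56)
  ctrl <- runif(50, 0, 0.2); trt <- runif(50, 0, 0.2)
  fwd <- classify_modulation(ctrl, trt)$direction
  rev <- classify_modulation(trt, ctrl)$direction
  map <- c(increased = "decreased", decreased = "increased",
           unaltered = "unaltered")
  expect_equal(unname(map[fwd]), rev)
})

test_that("differential tables cover all features and flag planted effects", {
  meta <- fix_meta(c("control", "butyrate", "acetate"), replicates = 4)
  set.seed(57)
  base <- c(f1 = 500, f2 = 2000, f3 = 100, f4 = 1000)
  mat <- sapply(seq_len(nrow(meta)), function(i) {
    mult <- if (meta$condition[i] == "butyrate") c(20, 1, 1, 1) else rep(1, 4)
    rmultinom(1, 50000, base * mult)[, 1]
  })
  dimnames(mat) <- list(names(base), meta$sample_id)
  tab <- abund_table(mat, meta = meta)
  dd <- differential_table(tab)

  # rows = features x non-control conditions
  expect_equal(nrow(dd), 4 * 2)
  planted <- dd[dd$feature == "f1" & dd$condition == "butyrate", ]
  expect_equal(planted$direction, "increased")
  expect_equal(planted$p_value, 2 / 70)

  # feature constant across all samples: unaltered with p = 1
  flat_mat <- matrix(5, 2, nrow(meta),
                     dimnames = list(c("a", "b"), meta$sample_id))
  flat <- differential_table(abund_table(flat_mat, meta = meta))
  expect_true(all(flat$direction == "unaltered"))
  expect_true(all(flat$p_value == 1))

  expect_error(differential_table(tab, control = "missing"), "control")

  s <- modulation_summary(dd)
  expect_equal(s$altered, s$increased + s$decreased)
  expect_equal(s$altered + s$unaltered, c(4, 4))
})
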