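logged_community <- function(seed = 20, n_otus = 60, sizes = rep(15, 3)) {
  sim <- generate_community(synth_spec(n_otus = n_otus, module_sizes = sizes,
                                       seed = seed))
  list(sim = sim, logged = log10_transform(fill_blanks(sim$otu)))
}

test_that("a rank-1 module has variance_explained 1 and its own profile", {
  prof <- rnorm(10)
  m <- rbind(a = prof, b = 2 * prof + 3, c = -prof)  # identical after scaling
  x <- toy_otu(abs(m) + 5)
  x$abundance <- m; x$log_scale <- TRUE
  rownames(x$abundance) <- c("a", "b", "c")
  part <- make_partition(c(a = 1L, b = 1L, c = 1L))
  eg <- module_eigengenes(x, part, min_size = 3)
  expect_equal(unname(eg$variance_explained["M1"]), 1)
  std <- as.numeric(scale(prof))
  e <- eg$eigengenes[, "M1"]
  expect_equal(abs(cor(e, std)), 1, tolerance = 1e-10)
  expect_equal(sum(e^2), 1)   # unit norm
})

test_that("two-member module has variance_explained (1 + |r|)/2", {
  set.seed(22)
  a <- rnorm(12)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(12)
  x <- toy_otu(rbind(a = a, b = b) + 10)
  part <- make_partition(c(a = 1L, b = 1L))
  eg <- module_eigengenes(x, part, min_size = 2)
  r <- abs(cor(as.numeric(scale(a)), as.numeric(scale(b))))
  expect_equal(unname(eg$variance_explained["M1"]), (1 + r) / 2,
               tolerance = 1e-10)
})

test_that("eigengene sign is fixed against the module mean profile", {
  lc <- logged_community()
  eg <- module_eigengenes(lc$logged, make_partition(lc$sim$truth$partition))
  for (j in seq_len(ncol(eg$eigengenes))) {
    m <- eg$modules[j]
    members <- names(lc$sim$truth$partition)[lc$sim$truth$partition == m]
    members <- intersect(members, rownames(lc$logged$abundance))
    prof <- colMeans(t(scale(t(lc$logged$abundance[members, ]))))
    expect_gte(cor(eg$eigengenes[, j], prof), 0)
  }
  # flipping all member profiles leaves the result observably unchanged
  flipped <- lc$logged
  flipped$abundance <- -flipped$abundance
  eg2 <- module_eigengenes(flipped, make_partition(lc$sim$truth$partition))
  expect_equal(unname(abs(diag(cor(eg$eigengenes, eg2$eigengenes)))),
               rep(1, ncol(eg$eigengenes)), tolerance = 1e-8)
})

test_that("variance explained grows with within-module correlation", {
  ve_at <- function(rho) {
    sim <- generate_community(synth_spec(n_otus = 40,
                                         module_sizes = rep(20, 2),
                                         within_module_correlation = rho,
                                         zero_inflation = 0, seed = 23))
    logged <- log10_transform(fill_blanks(sim$otu))
    eg <- module_eigengenes(logged, make_partition(sim$truth$partition))
    mean(eg$variance_explained)
  }
  expect_gt(ve_at(0.9), ve_at(0.5))
})

test_that("module-environment correlations find planted drivers", {
  lc <- logged_community(seed = 24, n_otus = 100, sizes = rep(25, 4))
  fitpart <- make_partition(lc$sim$truth$partition)
  eg <- module_eigengenes(lc$logged, fitpart)
  tab <- module_env_heatmap(eg, lc$sim$metadata)
  # a variable equal to an eigengene correlates perfectly
  md <- lc$sim$metadata
  md$variables$copy <- eg$eigengenes[md$sample_ids, "M3"]
  tab2 <- module_env_heatmap(eg, md)
  expect_equal(tab2$r[tab2$module == "M3" & tab2$variable == "copy"], 1,
               tolerance = 1e-12)
  # the planted T driver (module 1) is the most significant cell of its row
  rowT <- tab[tab$variable == "T", ]
  expect_identical(rowT$module[which.min(rowT$p)], "M1")
  # constant variable is reported as missing
  md$variables$const <- 5
  tab3 <- module_env_heatmap(eg, md)
  expect_true(all(is.na(tab3$r[tab3$variable == "const"])))
})

test_that("module-environment p-values are calibrated under independence", {
  set.seed(25)
  p <- replicate(400, cor.test(rnorm(15), rnorm(15))$p.value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})

test_that("eigengene hierarchy reflects pairwise correlation distances", {
  n <- 20
  set.seed(26)
  base <- rnorm(n)
  eg <- structure(list(
    eigengenes = cbind(M1 = base, M2 = base + rnorm(n, 0, 0.1),
                       M3 = rnorm(n)),
    variance_explained = c(M1 = 1, M2 = 1, M3 = 1), modules = 1:3),
    class = "module_eigengenes")
  eg$eigengenes <- apply(eg$eigengenes, 2, function(v) v / sqrt(sum(v^2)))
  h <- eigengene_hierarchy(eg)
  # M1 and M2 (most correlated) merge first
  expect_identical(sort(h$hclust$merge[1, ]), c(-2L, -1L))
  tree <- ape::read.tree(text = h$newick)
  expect_setequal(tree$tip.label, c("M1", "M2", "M3"))
  # identical eigengenes merge at height 0
  eg$eigengenes[, "M2"] <- eg$eigengenes[, "M1"]
  h2 <- eigengene_hierarchy(eg)
  expect_equal(h2$hclust$height[1], 0, tolerance = 1e-12)
})

test_that("Mantel r matches a manual lower-triangle computation", {
  m <- matrix(c(10, 2, 1,
                8, 4, 2,
                2, 9, 5,
                1, 10, 8), nrow = 3,
              dimnames = list(paste0("OTU", 1:3), paste0("S", 1:4)))
  x <- otu_table(m)
  v <- c(1.2, 0.8, -0.5, -1.1)
  mt <- mantel_test(x, v, n_permutations = 999, seed = 3)
  # manual: Bray-Curtis on relative abundances, Euclidean on scaled v
  rel <- sweep(m, 2, colSums(m), "/")
  bc <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    bc[i, j] <- sum(abs(rel[, i] - rel[, j])) / sum(rel[, i] + rel[, j])
  dv <- as.matrix(dist(as.numeric(scale(v))))
  lt <- lower.tri(bc)
  expect_equal(mt$mantel_r, cor(bc[lt], dv[lt]), tolerance = 1e-12)
  expect_gte(mt$p, 1 / 1000)
})

test_that("Mantel agrees with the vegan reference and detects self-distance", {
  sim <- generate_community(synth_spec(n_otus = 40, module_sizes = rep(10, 2),
                                       seed = 27))
  keep <- names(sim$otu$group)[sim$otu$group == "LC"]
  x <- otu_table(sim$otu$abundance[, keep])
  v <- rnorm(length(keep))
  mt <- mantel_test(x, v, seed = 4)
  ref <- vegan::mantel(as.dist(bray_curtis(x)),
                       dist(as.numeric(scale(v))),
                       method = "pearson", permutations = 999)
  expect_equal(mt$mantel_r, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mt$p, ref$signif, tolerance = 0.06)
  # a variable whose distances equal the community distances gives r = 1
  pc <- cmdscale(as.dist(bray_curtis(x)), k = 1)
  # use the community's own 1-d embedding: very high r, minimal-ish p
  mt2 <- mantel_test(x, pc[, 1], seed = 5)
  expect_gt(mt2$mantel_r, 0.5)
  expect_lte(mt2$p, 0.01)
  expect_error(mantel_test(x, rep(1, length(keep))), "constant")
})

test_that("Mantel r is invariant to a consistent sample relabeling", {
  sim <- generate_community(synth_spec(n_otus = 30, module_sizes = rep(10, 2),
                                       seed = 28))
  keep <- names(sim$otu$group)[sim$otu$group == "LC"]
  x <- otu_table(sim$otu$abundance[, keep])
  set.seed(1); v <- rnorm(length(keep))
  perm <- sample(length(keep))
  xp <- otu_table(sim$otu$abundance[, keep[perm]])
  r1 <- mantel_test(x, v, seed = 6)$mantel_r
  r2 <- mantel_test(xp, v[perm], seed = 6)$mantel_r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("group t-tests behave at the fixed points and under strong shifts", {
  vars <- data.frame(a = c(1, 2, 3, 1, 2, 3), b = c(0, 0, 1, 5, 5, 6))
  rownames(vars) <- paste0("S", 1:6)
  md <- sample_metadata(vars, group = setNames(rep(c("g1", "g2"), each = 3),
                                               paste0("S", 1:6)))
  tt <- group_ttests(md)
  expect_equal(tt$t[tt$variable == "a"], 0)
  expect_equal(tt$p[tt$variable == "a"], 1)
  expect_lt(tt$p[tt$variable == "b"], 0.001)
  expect_identical(tt$stars[tt$variable == "b"], "***")
  # group guards
  md$group[] <- "g1"
  expect_error(group_ttests(md), "exactly 2 groups")
})

test_that("summary-statistics t-test reproduces a significance tier", {
  # soil pH comparison: 7.20 +/- 0.30 vs 7.64 +/- 0.37, n = 15 per group
  res <- ttest_from_summary(7.20, 0.30, 15, 7.64, 0.37, 15)
  expect_lt(res$p, 0.01)
  expect_identical(res$df, 28)
  # oracle: feed two samples with exactly these moments to t.test
  mk <- function(m, s, n) m + s * scale(seq_len(n))[, 1]
  ref <- t.test(mk(7.20, 0.30, 15), mk(7.64, 0.37, 15), var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})
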