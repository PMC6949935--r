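test_that("network construction keeps exactly the qualifying pairs", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- -0.5
  sim <- make_sim(r)
  net <- build_network(sim, 0.81)
  expect_identical(net$nodes, c("OTU1", "OTU2"))
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 0.9)
  expect_equal(net$edges$sign, 1)
  empty <- build_network(sim, 0.95)
  expect_length(empty$nodes, 0L)
  # negative correlations carry their sign
  net2 <- build_network(sim, 0.45)
  e <- net2$edges
  expect_equal(e$sign[e$source == "OTU1" & e$target == "OTU3"], -1)
})

test_that("average degree and density follow their formulas", {
  expect_equal(average_degree(2, 1), 1)
  expect_equal(network_density(5, 10), 1)   # complete graph on 5 nodes
  expect_error(average_degree(0, 3), "positive")
  expect_error(network_density(1, 0), "at least 2")
})

test_that("clustering statistics match hand enumeration", {
  k3 <- make_net(c("a", "a", "b"), c("b", "c", "c"))
  cs <- clustering_stats(k3)
  expect_equal(cs$avg_clustering, 1)
  expect_equal(cs$transitivity, 1)

  path <- make_net(c("a", "b"), c("b", "c"))
  cs <- clustering_stats(path)
  expect_equal(cs$avg_clustering, 0)
  expect_equal(cs$transitivity, 0)

  # K3 plus a pendant on vertex a: local cc = (1/3, 1, 1, 0),
  # 1 triangle, 5 connected triples -> transitivity 3/5
  k3p <- make_net(c("a", "a", "b", "a"), c("b", "c", "c", "d"))
  cs <- clustering_stats(k3p)
  expect_equal(cs$avg_clustering, (1 / 3 + 1 + 1 + 0) / 4)
  expect_equal(cs$transitivity, 3 / 5)
})

test_that("path statistics match pair enumeration", {
  single <- make_net("a", "b")
  ps <- path_stats(single)
  expect_equal(unlist(ps), c(avg_path_distance = 1, geodesic_efficiency = 1,
                             connectedness = 1))

  two_edges <- make_net(c("a", "c"), c("b", "d"))
  ps <- path_stats(two_edges)
  expect_equal(ps$connectedness, 2 / 6)

  path3 <- make_net(c("a", "b"), c("b", "c"))
  ps <- path_stats(path3)
  expect_equal(ps$avg_path_distance, 4 / 3)
  expect_equal(ps$geodesic_efficiency, (1 + 1 + 0.5) / 3)
  expect_equal(ps$connectedness, 1)
})

test_that("power-law R2 is exact on an exact power law and guarded otherwise", {
  # degree frequencies f(k) = 64 k^-2 over k in {1, 2, 4, 8}: realize a
  # graph with exactly that degree sequence; log-log regression is exact
  degs <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
  g <- igraph::realize_degseq(degs)
  el <- igraph::as_edgelist(g)
  net <- make_net(paste0("v", el[, 1]), paste0("v", el[, 2]))
  expect_equal(suppressWarnings(powerlaw_r2(net)), 1, tolerance = 1e-12)
  # a cycle has a single distinct degree -> undefined
  cyc <- make_net(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  expect_warning(r2 <- powerlaw_r2(cyc), "3 distinct")
  expect_true(is.na(r2))
  # R2 on a synthetic network agrees with an independent OLS oracle
  sim <- generate_community(synth_spec(n_otus = 80, module_sizes = rep(20, 3),
                                       seed = 14))
  fit2 <- mena(sim$otu)
  deg <- igraph::degree(fit2$network$graph)
  tab <- table(deg[deg > 0])
  x <- log10(as.numeric(names(tab))); y <- log10(as.numeric(tab))
  b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
  ss_res <- sum((y - a - b * x)^2); ss_tot <- sum((y - mean(y))^2)
  expect_equal(powerlaw_r2(fit2$network), 1 - ss_res / ss_tot,
               tolerance = 1e-10)
})

test_that("greedy modules on the two-triangle bridge give the Newman Q", {
  net <- make_net(c("a", "a", "b", "c", "d", "d", "e"),
                  c("b", "c", "c", "d", "e", "f", "f"))
  part <- detect_modules(net)
  expect_identical(part$n_modules, 2L)
  expect_identical(sort(part$sizes), c(3L, 3L))
  expect_equal(part$modularity, 2 * (3 / 7 - (7 / 14)^2), tolerance = 1e-12)
  expect_equal(newman_modularity(net, part$membership), part$modularity)
  # same partition by hand evaluation of Q = sum_c (e_c/m - (d_c/2m)^2)
  expect_equal(part$modularity, 0.35714286, tolerance = 1e-6)
})

test_that("a complete graph has no community structure", {
  n <- 5
  pairs <- t(combn(paste0("v", 1:n), 2))
  net <- make_net(pairs[, 1], pairs[, 2])
  part <- detect_modules(net)
  # any partition of a complete graph scores Q <= 0; greedy merging stops
  # at a zero-gain configuration
  expect_lte(part$modularity, 1e-12)
  trivial <- setNames(rep(1L, n), paste0("v", 1:n))
  expect_lte(part$modularity, newman_modularity(net, trivial) + 1e-12)
})

test_that("module detection modularity beats the trivial partition", {
  for (s in c(3, 7)) {
    net <- random_graph_net(30, 0.15, seed = s)
    part <- detect_modules(net)
    trivial <- setNames(rep(1L, length(net$nodes)), net$nodes)
    expect_gte(part$modularity, newman_modularity(net, trivial))
  }
})

test_that("metrics agree with brute-force oracles on random graphs", {
  brute <- function(net) {
    ids <- net$nodes
    n <- length(ids)
    adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    for (e in seq_len(nrow(net$edges))) {
      adj[net$edges$source[e], net$edges$target[e]] <- TRUE
      adj[net$edges$target[e], net$edges$source[e]] <- TRUE
    }
    # BFS distances
    d <- matrix(Inf, n, n); diag(d) <- 0
    for (s in 1:n) {
      frontier <- s; dist <- 0
      while (length(frontier)) {
        dist <- dist + 1
        nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ]))))
        nxt <- nxt[d[s, nxt] == Inf]
        d[s, nxt] <- dist
        frontier <- nxt
      }
    }
    # triangles and triples
    tri <- 0; triples <- 0; local_cc <- numeric(n)
    for (v in 1:n) {
      nb <- which(adj[v, ]); k <- length(nb)
      triples <- triples + choose(k, 2)
      if (k >= 2) {
        links <- sum(adj[nb, nb]) / 2
        tri <- tri + links
        local_cc[v] <- links / choose(k, 2)
      }
    }
    ut <- upper.tri(d)
    reach <- is.finite(d[ut])
    list(avg_clustering = mean(local_cc),
         transitivity = if (triples > 0) tri / triples else 0,
         avg_path = mean(d[ut][reach]),
         efficiency = mean(ifelse(reach, 1 / d[ut], 0)),
         connectedness = mean(reach))
  }
  for (s in 1:8) {
    net <- random_graph_net(n = 10 + 3 * s, p = 0.12, seed = 100 + s)
    if (is.null(net)) next
    o <- brute(net)
    cs <- clustering_stats(net)
    ps <- path_stats(net)
    expect_equal(cs$avg_clustering, o$avg_clustering, tolerance = 1e-12)
    expect_equal(cs$transitivity, o$transitivity, tolerance = 1e-12)
    expect_equal(ps$avg_path_distance, o$avg_path, tolerance = 1e-12)
    expect_equal(ps$geodesic_efficiency, o$efficiency, tolerance = 1e-12)
    expect_equal(ps$connectedness, o$connectedness, tolerance = 1e-12)
  }
})

test_that("topology panel satisfies its internal identities", {
  sim <- generate_community(synth_spec(n_otus = 80, module_sizes = rep(20, 3),
                                       seed = 15))
  fit <- mena(sim$otu)
  tp <- fit$topology
  n <- tp$total_nodes; l <- tp$total_links
  expect_equal(tp$avg_degree, round(2 * l / n, 3))
  expect_equal(tp$density, round(l / (n * (n - 1) / 2), 3))
  expect_gte(tp$maximal_degree, tp$avg_degree)
  expect_true(tp$connectedness >= 0 && tp$connectedness <= 1)
  expect_true(tp$transitivity >= 0 && tp$transitivity <= 1)
  conn <- igraph::is_connected(fit$network$graph)
  expect_identical(tp$connectedness == 1, conn)
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(50)
  for (i in 1:5) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(menet:::adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(menet:::adjusted_rand_index(1:10, 1:10), 1)
})
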