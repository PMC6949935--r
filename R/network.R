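#' Build a co-occurrence network from a similarity matrix
#'
#' Nodes are OTUs with at least one pairwise similarity at or above the
#' threshold; edges carry the similarity as weight and the sign of the
#' underlying correlation. All topology metrics are computed on the
#' unweighted skeleton (edge present/absent); weights are retained for
#' export.
#'
#' @param sim a `similarity_matrix` from [pearson_similarity()].
#' @param threshold similarity cutoff in (0, 1).
#' @param taxonomy optional named lineage vector used to attach a phylum
#'   label to each node (see [parse_phylum()]).
#' @return an object of class `eco_network` with fields `nodes`, `edges`
#'   (data.frame: source, target, weight, sign), `graph` (igraph),
#'   `threshold`, `node_taxa`. Zero-node networks are returned, not errors.
#' @export
build_network <- function(sim, threshold, taxonomy = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (!(threshold > 0 && threshold < 1))
    stop("`threshold` must lie strictly between 0 and 1")
  v <- sim$values
  diag(v) <- 0
  idx <- which(v >= threshold & upper.tri(v), arr.ind = TRUE)
  edges <- data.frame(
    source = sim$otu_ids[idx[, 1]],
    target = sim$otu_ids[idx[, 2]],
    weight = v[idx],
    sign = sim$sign[idx],
    stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$source, edges$target)))
  nodes <- sim$otu_ids[sim$otu_ids %in% nodes]   # keep input order
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  node_taxa <- NULL
  if (!is.null(taxonomy)) {
    node_taxa <- stats::setNames(parse_phylum(taxonomy[nodes]), nodes)
    node_taxa[is.na(taxonomy[nodes])] <- "Unclassified"
  }
  structure(list(nodes = nodes, edges = edges, graph = g,
                 threshold = threshold, node_taxa = node_taxa),
            class = "eco_network")
}

#' @export
print.eco_network <- function(x, ...) {
  if (length(x$nodes) == 0) {
    cat("Empty ecological network (no similarity reached the threshold ",
        format(x$threshold), ")\n", sep = "")
  } else {
    cat(sprintf("Ecological network: %d nodes, %d links (threshold %s)\n",
                length(x$nodes), nrow(x$edges), format(x$threshold)))
  }
  invisible(x)
}

#' Average degree of a network
#'
#' `2 L / N` for `N` nodes and `L` links; the headline connectivity figure
#' of the topology panel.
#'
#' @param n_nodes,n_links integers.
#' @param digits rounding for reporting (3 decimals in the standard panel).
#' @export
average_degree <- function(n_nodes, n_links, digits = 3) {
  if (n_nodes <= 0) stop("`n_nodes` must be positive")
  round(2 * n_links / n_nodes, digits)
}

#' Density of a network
#'
#' Fraction of realized node pairs, `L / (N (N - 1) / 2)`.
#'
#' @inheritParams average_degree
#' @export
network_density <- function(n_nodes, n_links, digits = 3) {
  if (n_nodes < 2) stop("`n_nodes` must be at least 2")
  round(n_links / (n_nodes * (n_nodes - 1) / 2), digits)
}

#' Clustering statistics
#'
#' Average local clustering coefficient (nodes of degree < 2 contribute 0)
#' and global transitivity (3 x triangles / connected triples).
#'
#' @param net an `eco_network`.
#' @return list with `avg_clustering` and `transitivity`.
#' @export
clustering_stats <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[is.na(loc)] <- 0
  glob <- igraph::transitivity(g, type = "global")
  if (is.na(glob)) glob <- 0
  list(avg_clustering = mean(loc), transitivity = glob)
}

#' Shortest-path statistics
#'
#' Unweighted geodesics. The average path distance is taken over reachable
#' unordered pairs; geodesic efficiency averages `1/d` over all pairs with
#' `1/Inf = 0`; connectedness is Krackhardt's fraction of reachable pairs.
#'
#' @param net an `eco_network`.
#' @return list with `avg_path_distance`, `geodesic_efficiency`,
#'   `connectedness`.
#' @export
path_stats <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0) stop("empty network")
  if (n == 1) return(list(avg_path_distance = NaN, geodesic_efficiency = NaN,
                          connectedness = 1))
  d <- igraph::distances(g, weights = NA)
  d <- d[upper.tri(d)]
  reach <- is.finite(d)
  list(avg_path_distance = mean(d[reach]),
       geodesic_efficiency = mean(ifelse(reach, 1 / d, 0)),
       connectedness = mean(reach))
}

#' R-squared of the power-law degree-distribution fit
#'
#' Ordinary least squares of log10(frequency) on log10(degree) over the
#' non-zero-frequency degrees; the usual scale-free credibility figure.
#'
#' @param net an `eco_network`.
#' @return R-squared in \[0, 1\], or `NA` (with a warning) when fewer than
#'   3 distinct degrees occur.
#' @export
powerlaw_r2 <- function(net) {
  deg <- igraph::degree(net$graph)
  tab <- table(deg[deg > 0])
  if (length(tab) < 3) {
    warning("fewer than 3 distinct degrees; power-law fit undefined")
    return(NA_real_)
  }
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  fit <- stats::lm(log10(f) ~ log10(k))
  summary(fit)$r.squared
}

#' Detect modules by greedy modularity maximisation
#'
#' Agglomerative (CNM-style) modularity optimisation on the unweighted
#' skeleton; deterministic for a given graph. Modularity Q is Newman's
#' `sum_c (e_c / m - (d_c / 2m)^2)`.
#'
#' @param net an `eco_network`.
#' @param method `"greedy"` (default) or `"eigen"` (leading eigenvector).
#' @return an object of class `module_partition`: named membership vector
#'   `membership`, `sizes`, `modularity`, `n_modules`, and
#'   `n_modules_large` (modules with more than 5 nodes, the reporting rule
#'   used for module-level analyses).
#' @export
detect_modules <- function(net, method = c("greedy", "eigen")) {
  method <- match.arg(method)
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  cl <- switch(method,
               greedy = igraph::cluster_fast_greedy(g, weights = NA),
               eigen = igraph::cluster_leading_eigen(g, weights = NA))
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  q <- igraph::modularity(g, memb, weights = NULL)
  structure(list(membership = stats::setNames(as.integer(memb),
                                              names(memb)),
                 sizes = as.integer(sizes),
                 modularity = q,
                 n_modules = length(sizes),
                 n_modules_large = sum(sizes > 5)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules (%d with > 5 nodes), Q = %.3f\n",
              x$n_modules, x$n_modules_large, x$modularity))
  invisible(x)
}

#' Newman modularity of a given partition
#'
#' Direct evaluation of `Q = sum_c (e_c / m - (d_c / 2m)^2)`; used to score
#' arbitrary partitions (including the planted truth of synthetic data).
#'
#' @param net an `eco_network`.
#' @param membership named integer vector over the network nodes.
#' @export
newman_modularity <- function(net, membership) {
  igraph::modularity(net$graph, membership[net$nodes], weights = NULL)
}

#' Assemble the topology panel
#'
#' The standard reporting panel of an RMT co-occurrence network: node and
#' link counts, power-law R-squared, average degree, clustering, path
#' statistics, density, transitivity, connectedness, maximal degree, module
#' count and modularity. Real-valued entries are rounded to 3 decimals.
#'
#' @param net an `eco_network`.
#' @param partition a `module_partition` (computed when missing).
#' @param n_original_otus OTU count before thresholding, for the record.
#' @return a one-row data.frame.
#' @export
topology_panel <- function(net, partition = NULL, n_original_otus = NA) {
  if (length(net$nodes) == 0) stop("empty network")
  if (is.null(partition)) partition <- detect_modules(net)
  n <- length(net$nodes)
  l <- nrow(net$edges)
  cs <- clustering_stats(net)
  ps <- path_stats(net)
  data.frame(
    n_original_otus = n_original_otus,
    similarity_threshold = net$threshold,
    total_nodes = n,
    total_links = l,
    r_square_power_law = round(suppressWarnings(powerlaw_r2(net)), 3),
    avg_degree = average_degree(n, l),
    avg_clustering = round(cs$avg_clustering, 3),
    avg_path_distance = round(ps$avg_path_distance, 3),
    geodesic_efficiency = round(ps$geodesic_efficiency, 3),
    maximal_degree = max(igraph::degree(net$graph)),
    density = network_density(n, l),
    transitivity = round(cs$transitivity, 3),
    connectedness = round(ps$connectedness, 3),
    n_modules = partition$n_modules,
    n_modules_large = partition$n_modules_large,
    modularity = round(partition$modularity, 3))
}

# Adjusted Rand index between two labelings (internal; used for
# planted-partition recovery checks).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
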