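# small builders used across the suite

toy_otu <- function(mat, otu_prefix = "OTU", sample_prefix = "S", ...) {
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0(otu_prefix, seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0(sample_prefix, seq_len(ncol(mat)))
  otu_table(mat, ...)
}

# an eco_network directly from a character edge list (unit weights)
make_net <- function(from, to, weight = 0.9, sign = 1, threshold = 0.8) {
  edges <- data.frame(source = from, target = to,
                      weight = rep_len(weight, length(from)),
                      sign = rep_len(sign, length(from)),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(from, to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(nodes = nodes, edges = edges, graph = g,
                 threshold = threshold, node_taxa = NULL),
            class = "eco_network")
}

make_partition <- function(membership) {
  sizes <- as.integer(table(membership))
  structure(list(membership = membership, sizes = sizes,
                 modularity = NA_real_, n_modules = length(sizes),
                 n_modules_large = sum(sizes > 5)),
            class = "module_partition")
}

# similarity_matrix straight from a symmetric matrix of signed correlations
make_sim <- function(r, ids = NULL) {
  if (is.null(ids)) ids <- paste0("OTU", seq_len(nrow(r)))
  dimnames(r) <- list(ids, ids)
  v <- abs(r); diag(v) <- 1
  structure(list(otu_ids = ids, values = v, sign = sign(r)),
            class = "similarity_matrix")
}

random_graph_net <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- runif(n * (n - 1) / 2) < p
  idx <- which(a == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  ids <- paste0("n", seq_len(n))
  make_net(ids[idx[, 1]], ids[idx[, 2]])
}
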