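#' Fit a molecular ecological network to an OTU table
#'
#' The central fitting function: prevalence filtering, blank filling, log10
#' transform, Pearson similarity, similarity-threshold choice (fixed, or by
#' the random-matrix-theory spacing scan), network construction, greedy
#' module detection, the full topology panel, Zi-Pi node roles, and — when
#' metadata are supplied — module eigengenes with their environmental
#' correlations and per-variable Mantel tests.
#'
#' @param otu an [otu_table] (raw counts or relative abundances).
#' @param metadata optional [sample_metadata] over the same samples.
#' @param threshold fixed similarity cutoff (default 0.81, the conventional
#'   setting when two groups must stay comparable); ignored when
#'   `threshold_mode = "scan"`.
#' @param threshold_mode `"fixed"` (default) or `"scan"` (RMT scan from the
#'   top; see [scan_threshold()]).
#' @param min_present prevalence rule, see [prevalence_filter()].
#' @param fill_value blank fill, see [fill_blanks()].
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param scan_from,scan_to,scan_step,rmt_alpha scan settings.
#' @param min_module_size smallest module summarised by an eigengene.
#' @param mantel_permutations permutations for [mantel_table()].
#' @param seed seed for every stochastic step (permutations).
#' @return an object of class `mena`; see [summary.mena()].
#' @examples
#' sim <- generate_community(synth_spec(n_otus = 60, module_sizes = rep(15, 3)))
#' fit <- mena(sim$otu)
#' summary(fit)
#' @export
mena <- function(otu, metadata = NULL,
                 threshold = 0.81,
                 threshold_mode = c("fixed", "scan"),
                 min_present = NULL,
                 fill_value = 0.01,
                 cor_method = c("pearson", "spearman"),
                 scan_from = 0.99, scan_to = 0.30, scan_step = 0.01,
                 rmt_alpha = 0.05,
                 min_module_size = 6,
                 mantel_permutations = 999,
                 seed = 1) {
  stopifnot(inherits(otu, "otu_table"))
  threshold_mode <- match.arg(threshold_mode)
  cor_method <- match.arg(cor_method)
  cl <- match.call()

  filtered <- prevalence_filter(otu, min_present)
  filled <- fill_blanks(filtered, fill_value)
  logged <- log10_transform(filled)
  sim <- pearson_similarity(logged, method = cor_method)

  scan <- NULL
  if (threshold_mode == "scan") {
    scan <- scan_threshold(sim, scan_from = scan_from, scan_to = scan_to,
                           step = scan_step, alpha = rmt_alpha)
    if (is.na(scan$selected_threshold))
      stop("RMT scan selected no threshold; supply a fixed one")
    threshold <- scan$selected_threshold
  }

  net <- build_network(sim, threshold, taxonomy = otu$taxonomy)
  if (length(net$nodes) == 0)
    stop("no similarity reached the threshold ", threshold,
         "; the network is empty")
  partition <- detect_modules(net)
  panel <- topology_panel(net, partition, n_original_otus = nrow(filtered$abundance))
  roles <- zp_table(net, partition, taxonomy = otu$taxonomy)

  eigengenes <- env_cor <- mantel <- hierarchy <- ttests <- NULL
  if (any(partition$sizes >= min_module_size)) {
    eigengenes <- suppressWarnings(
      module_eigengenes(logged, partition, min_size = min_module_size))
    if (ncol(eigengenes$eigengenes) >= 2)
      hierarchy <- eigengene_hierarchy(eigengenes)
  }
  if (!is.null(metadata)) {
    stopifnot(inherits(metadata, "sample_metadata"))
    if (!all(sample_ids(otu) %in% metadata$sample_ids))
      stop("metadata does not cover the OTU-table samples")
    if (!is.null(eigengenes))
      env_cor <- module_env_heatmap(eigengenes, metadata)
    mantel <- mantel_table(otu, metadata,
                           n_permutations = mantel_permutations, seed = seed)
    if (!is.null(metadata$group) &&
        length(unique(stats::na.omit(metadata$group))) == 2)
      ttests <- group_ttests(metadata)
  }

  structure(list(call = cl, otu = otu, filtered = filtered, logged = logged,
                 similarity = sim, scan = scan, threshold = threshold,
                 threshold_mode = threshold_mode,
                 network = net, partition = partition, topology = panel,
                 roles = roles, eigengenes = eigengenes,
                 hierarchy = hierarchy, env_cor = env_cor, mantel = mantel,
                 ttests = ttests,
                 config = list(min_present = min_present,
                               fill_value = fill_value,
                               cor_method = cor_method,
                               rmt_alpha = rmt_alpha,
                               min_module_size = min_module_size,
                               mantel_permutations = mantel_permutations,
                               seed = seed)),
            class = "mena")
}

#' @export
print.mena <- function(x, ...) {
  cat("Molecular ecological network fit\n")
  cat(sprintf("  threshold: %s (%s)\n", format(x$threshold), x$threshold_mode))
  cat(sprintf("  %d nodes, %d links, %d modules (Q = %.3f)\n",
              x$topology$total_nodes, x$topology$total_links,
              x$partition$n_modules, x$partition$modularity))
  rc <- attr(x$roles, "role_counts")
  cat("  roles:", paste(names(rc), rc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a molecular ecological network fit
#'
#' @param object a `mena` fit.
#' @param ... unused.
#' @return an object of class `summary.mena` printing the topology panel,
#'   role counts and (when available) the environmental linkage tables.
#' @export
summary.mena <- function(object, ...) {
  structure(list(topology = object$topology,
                 role_counts = attr(object$roles, "role_counts"),
                 env_cor = object$env_cor,
                 mantel = object$mantel,
                 ttests = object$ttests),
            class = "summary.mena")
}

#' @export
print.summary.mena <- function(x, ...) {
  cat("Topology panel:\n")
  print(as.data.frame(t(x$topology)))
  cat("\nNode roles:\n")
  print(x$role_counts)
  if (!is.null(x$mantel)) {
    cat("\nMantel tests (community vs. environment):\n")
    print(x$mantel, row.names = FALSE)
  }
  if (!is.null(x$env_cor)) {
    sig <- x$env_cor[!is.na(x$env_cor$p) & x$env_cor$p < 0.05, ]
    cat("\nModule-environment correlations significant at 0.05: ",
        nrow(sig), " of ", nrow(x$env_cor), "\n", sep = "")
  }
  invisible(x)
}

#' Plot aspects of a molecular ecological network fit
#'
#' `type = "zp"` draws the Zi-Pi role scatter with the 2.5 / 0.62 guides;
#' `"degree"` the log-log degree distribution with the power-law fit;
#' `"heatmap"` the module-environment correlation matrix.
#'
#' @param x a `mena` fit.
#' @param type one of `"zp"`, `"degree"`, `"heatmap"`.
#' @param ... passed to the underlying base-graphics calls.
#' @export
plot.mena <- function(x, type = c("zp", "degree", "heatmap"), ...) {
  type <- match.arg(type)
  if (type == "zp") {
    plot(x$roles$pi, x$roles$zi, xlab = "Among-module connectivity (Pi)",
         ylab = "Within-module connectivity (Zi)", xlim = c(0, 1),
         pch = 19, col = factor(x$roles$role), ...)
    graphics::abline(h = 2.5, v = 0.62, lty = 2)
  } else if (type == "degree") {
    deg <- igraph::degree(x$network$graph)
    tab <- table(deg[deg > 0])
    k <- as.numeric(names(tab)); f <- as.numeric(tab)
    plot(log10(k), log10(f), xlab = "log10 degree", ylab = "log10 frequency",
         pch = 19, ...)
    if (length(tab) >= 3)
      graphics::abline(stats::lm(log10(f) ~ log10(k)), lty = 2)
  } else {
    if (is.null(x$env_cor)) stop("no module-environment correlations in fit")
    r <- stats::xtabs(r ~ module + variable, data = x$env_cor)
    graphics::image(seq_len(nrow(r)), seq_len(ncol(r)), unclass(r),
                    axes = FALSE, xlab = "", ylab = "",
                    col = grDevices::hcl.colors(21, "Blue-Red"),
                    zlim = c(-1, 1), ...)
    graphics::axis(1, seq_len(nrow(r)), rownames(r))
    graphics::axis(2, seq_len(ncol(r)), colnames(r), las = 2)
  }
  invisible(x)
}
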