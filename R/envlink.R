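#' Module eigengenes
#'
#' A module's eigengene is the leading left singular vector of the
#' samples x members matrix of standardized member-OTU profiles: a
#' one-vector summary of the module's abundance behaviour across samples.
#' The sign is fixed so the eigengene correlates non-negatively with the
#' module's mean standardized profile. Only modules with more than
#' `min_size - 1` nodes (default: more than 5) are summarised; smaller ones
#' are skipped with a warning.
#'
#' @param x an [otu_table] on the scale used for the network (filled,
#'   log10-transformed).
#' @param partition a `module_partition`.
#' @param min_size minimum module size to summarise (default 6, i.e. the
#'   "more than five nodes" reporting rule).
#' @return an object of class `module_eigengenes`: matrix `eigengenes`
#'   (samples x modules, unit-norm columns) and numeric
#'   `variance_explained` per module.
#' @export
module_eigengenes <- function(x, partition, min_size = 6) {
  stopifnot(inherits(x, "otu_table"))
  memb <- partition$membership
  memb <- memb[names(memb) %in% otu_ids(x)]
  mods <- sort(unique(memb))
  keep <- mods[vapply(mods, function(m) sum(memb == m) >= min_size, logical(1))]
  skipped <- setdiff(mods, keep)
  if (length(skipped))
    warning("skipping ", length(skipped),
            " module(s) with fewer than ", min_size, " nodes")
  if (!length(keep)) stop("no module large enough to summarise")
  eg <- matrix(NA_real_, nrow = n_samples(x), ncol = length(keep),
               dimnames = list(sample_ids(x), paste0("M", keep)))
  ve <- stats::setNames(numeric(length(keep)), paste0("M", keep))
  for (i in seq_along(keep)) {
    members <- names(memb)[memb == keep[i]]
    prof <- t(scale(t(x$abundance[members, , drop = FALSE])))  # per-OTU z-score
    sv <- svd(t(prof))                         # samples x members
    e <- sv$u[, 1]
    if (stats::cor(e, rowMeans(t(prof))) < 0) e <- -e
    eg[, i] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = eg, variance_explained = ve,
                 modules = keep),
            class = "module_eigengenes")
}

#' @export
print.module_eigengenes <- function(x, ...) {
  cat(sprintf("Module eigengenes: %d modules x %d samples; var explained %s\n",
              ncol(x$eigengenes), nrow(x$eigengenes),
              paste(sprintf("%.2f", x$variance_explained), collapse = ", ")))
  invisible(x)
}

#' Module-environment correlation table
#'
#' Pearson correlation (pairwise-complete) between each module eigengene
#' and each environmental variable, with the two-tailed t-distribution
#' p-value — the table behind the module-trait heatmap. Constant variables
#' give `NA` entries.
#'
#' @param eigengenes a `module_eigengenes`.
#' @param metadata a [sample_metadata] whose samples match the eigengenes.
#' @return long data.frame (module, variable, r, p, stars).
#' @export
module_env_heatmap <- function(eigengenes, metadata) {
  stopifnot(inherits(eigengenes, "module_eigengenes"),
            inherits(metadata, "sample_metadata"))
  eg <- eigengenes$eigengenes
  if (!all(rownames(eg) %in% metadata$sample_ids))
    stop("metadata does not cover the eigengene samples")
  vars <- metadata$variables[rownames(eg), , drop = FALSE]
  out <- list()
  for (m in colnames(eg)) for (v in names(vars)) {
    x <- eg[, m]; y <- vars[[v]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    out[[length(out) + 1L]] <- data.frame(module = m, variable = v,
                                          r = r, p = p,
                                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out$stars <- significance_stars(out$p)
  out
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Eigengene hierarchy
#'
#' Average-linkage hierarchical clustering of module eigengenes on the
#' distance `1 - r` (Pearson), summarising how modules co-vary across
#' samples; exported as a Newick string for generic tree tools.
#'
#' @param eigengenes a `module_eigengenes` with at least 2 modules.
#' @return list with `hclust` (the tree) and `newick` (text form).
#' @export
eigengene_hierarchy <- function(eigengenes) {
  eg <- eigengenes$eigengenes
  if (ncol(eg) < 2) stop("need at least 2 module eigengenes")
  d <- stats::as.dist(1 - stats::cor(eg))
  hc <- stats::hclust(d, method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = newick)
}

#' Mantel test between community structure and one environmental variable
#'
#' Community distance is Bray-Curtis on relative OTU abundances; variable
#' distance is Euclidean on the standardized variable. The statistic is the
#' Pearson correlation of the two lower triangles; significance comes from
#' jointly permuting rows and columns of the community matrix, one-tailed:
#' `p = (#{r_perm >= r_obs} + 1) / (n_permutations + 1)`.
#'
#' @param x an [otu_table] of raw abundances (at least 4 samples).
#' @param variable numeric vector over the samples of `x`.
#' @param n_permutations permutation count (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list (`mantel_result`): `mantel_r`, `p`, `n_permutations`, `seed`.
#' @export
mantel_test <- function(x, variable, n_permutations = 999, seed = 1) {
  stopifnot(inherits(x, "otu_table"))
  n <- n_samples(x)
  if (n < 4) stop("need at least 4 samples for a Mantel test")
  if (length(variable) != n) stop("variable length must equal sample count")
  if (stats::sd(variable, na.rm = TRUE) == 0)
    stop("constant environmental variable; Mantel correlation undefined")
  dc <- bray_curtis(x)
  zv <- as.numeric(scale(variable))
  dv <- as.matrix(stats::dist(zv))
  lt <- lower.tri(dc)
  e <- dv[lt]
  r_obs <- stats::cor(dc[lt], e)
  set.seed(seed)
  ec <- e - mean(e)
  en <- sqrt(sum(ec^2))
  perm <- matrix(NA_real_, nrow = sum(lt), ncol = n_permutations)
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(n)
    perm[, b] <- dc[idx, idx][lt]
  }
  pc <- sweep(perm, 2, colMeans(perm))
  r_perm <- as.vector(crossprod(pc, ec)) /
    (sqrt(colSums(pc^2)) * en)
  p <- (sum(r_perm >= r_obs) + 1) / (n_permutations + 1)
  structure(list(mantel_r = r_obs, p = p,
                 n_permutations = n_permutations, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.3f (%d permutations)\n",
              x$mantel_r, x$p, x$n_permutations))
  invisible(x)
}

#' Mantel tests for every environmental variable
#'
#' One row per variable, the shape of the standard community-vs-environment
#' Mantel table.
#'
#' @param x an [otu_table].
#' @param metadata a [sample_metadata] over the same samples.
#' @param n_permutations,seed passed to [mantel_test()]; the seed is
#'   advanced per variable so tests are independent but reproducible.
#' @return data.frame (variable, mantel_r, p, stars).
#' @export
mantel_table <- function(x, metadata, n_permutations = 999, seed = 1) {
  vars <- metadata$variables[sample_ids(x), , drop = FALSE]
  rows <- lapply(seq_along(vars), function(i) {
    v <- vars[[i]]
    if (anyNA(v) || stats::sd(v) == 0)
      return(data.frame(variable = names(vars)[i], mantel_r = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    mt <- mantel_test(x, v, n_permutations = n_permutations, seed = seed + i)
    data.frame(variable = names(vars)[i], mantel_r = mt$mantel_r, p = mt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- significance_stars(out$p)
  out
}

#' Two-sample t-tests on environmental variables between groups
#'
#' Student's pooled-variance t-test (Welch optional) per variable, with the
#' mean +/- sd summaries and significance stars of the conventional
#' soil-properties comparison table.
#'
#' @param metadata a [sample_metadata] with a group label taking exactly two
#'   values.
#' @param var.equal pooled variance (TRUE, default) or Welch.
#' @return data.frame (variable, mean_sd per group, t, p, stars).
#' @export
group_ttests <- function(metadata, var.equal = TRUE) {
  stopifnot(inherits(metadata, "sample_metadata"))
  if (is.null(metadata$group)) stop("metadata carries no group labels")
  g <- factor(metadata$group[metadata$sample_ids])
  if (nlevels(g) != 2) stop("need exactly 2 groups, got ", nlevels(g))
  if (any(table(g) < 2)) stop("each group needs at least 2 samples")
  lv <- levels(g)
  rows <- lapply(names(metadata$variables), function(v) {
    y <- metadata$variables[[v]]
    y1 <- y[g == lv[1]]; y2 <- y[g == lv[2]]
    tt <- stats::t.test(y1, y2, var.equal = var.equal)
    data.frame(variable = v,
               group1 = sprintf("%.2f ± %.2f", mean(y1, na.rm = TRUE),
                                stats::sd(y1, na.rm = TRUE)),
               group2 = sprintf("%.2f ± %.2f", mean(y2, na.rm = TRUE),
                                stats::sd(y2, na.rm = TRUE)),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- lv
  out$stars <- significance_stars(out$p)
  out
}

#' Student's t-test from printed summary statistics
#'
#' Pooled two-sample t-test reconstructed from group means, standard
#' deviations and sizes — for checking published comparison tables whose
#' raw data are unavailable.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list with `t`, `df`, `p` (two-tailed).
#' @examples
#' ttest_from_summary(7.20, 0.30, 15, 7.64, 0.37, 15)
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
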