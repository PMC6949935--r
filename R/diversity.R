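#' Chao1 richness estimator
#'
#' `S_obs + F1^2 / (2 F2)` with F1 singletons and F2 doubletons; when no
#' doubletons occur the bias-corrected form `S_obs + F1 (F1 - 1) / 2` is
#' used. Requires count data.
#'
#' @param counts non-negative integer abundances of one sample.
#' @return the estimate (a real number).
#' @examples
#' chao1(c(1, 1, 2, 3))  # 6
#' @export
chao1 <- function(counts) {
  check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator with the classical formula: species
#' with abundance at most `rare_cutoff` form the rare class;
#' `ACE = S_abund + S_rare / C + (F1 / C) * gamma^2` with coverage
#' `C = 1 - F1 / N_rare` and `gamma^2` the rare-class coefficient of
#' variation `max(0, S_rare/C * sum(i (i-1) F_i) / (N_rare (N_rare - 1)) - 1)`.
#' When the coverage is zero (all rare species are singletons) the function
#' falls back to Chao1 with a warning.
#'
#' @param counts non-negative integer abundances.
#' @param rare_cutoff abundance bound of the rare class (default 10).
#' @return the estimate.
#' @export
ace <- function(counts, rare_cutoff = 10) {
  check_counts(counts)
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("ACE coverage is zero (all rare species are singletons); ",
            "falling back to Chao1")
    return(chao1(counts))
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  g2 <- max(s_rare / c_ace * sum(seq_len(rare_cutoff) *
                                   (seq_len(rare_cutoff) - 1) * fi) /
              (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

check_counts <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("richness estimators need raw non-negative integer counts")
  invisible(counts)
}

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i`, natural log by default (`base` toggles).
#'
#' @param counts abundances of one sample.
#' @param base logarithm base.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (sum(counts) <= 0) stop("total abundance must be positive")
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' Simpson index (dominance form)
#'
#' Dominance `D = sum p_i^2`: smaller means a more even community. The
#' complement `1 - D` is available via `complement = TRUE`.
#'
#' @param counts abundances of one sample.
#' @param complement return `1 - D` instead of `D`.
#' @export
simpson <- function(counts, complement = FALSE) {
  if (sum(counts) <= 0) stop("total abundance must be positive")
  one_minus_d <- unname(vegan::diversity(counts, index = "simpson"))
  if (complement) one_minus_d else 1 - one_minus_d
}

#' Alpha-diversity table
#'
#' Per-sample observed richness, Chao1, ACE, Shannon, and Simpson (both the
#' dominance D and 1 - D), computed on raw counts.
#'
#' @param x an [otu_table] of integer counts.
#' @return data.frame, one row per sample.
#' @export
alpha_diversity <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  res <- lapply(sample_ids(x), function(s) {
    v <- x$abundance[, s]
    data.frame(sample = s,
               s_obs = sum(v > 0),
               chao1 = chao1(v),
               ace = ace(v),
               shannon = shannon(v),
               simpson_d = simpson(v),
               simpson_1_minus_d = simpson(v, complement = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Rarefaction curve by resampling
#'
#' Seeded subsampling without replacement at the requested depths; reports
#' the mean and sd of observed richness per depth. Depths exceeding the
#' sample total are skipped with a warning.
#'
#' @param counts integer abundances of one sample.
#' @param depths subsampling depths.
#' @param n_resamples resamples per depth.
#' @param seed RNG seed.
#' @return data.frame (depth, mean_richness, sd_richness).
#' @export
rarefaction_curve <- function(counts, depths, n_resamples = 100, seed = 1) {
  check_counts(counts)
  total <- sum(counts)
  bad <- depths > total
  if (any(bad)) {
    warning("skipping depths exceeding the sample total: ",
            paste(depths[bad], collapse = ", "))
    depths <- depths[!bad]
  }
  pool <- rep(seq_along(counts), counts)
  set.seed(seed)
  rows <- lapply(depths, function(d) {
    rich <- replicate(n_resamples, length(unique(sample(pool, d))))
    data.frame(depth = d, mean_richness = mean(rich),
               sd_richness = stats::sd(rich))
  })
  do.call(rbind, rows)
}

#' Expected rarefied richness (hypergeometric closed form)
#'
#' `E[S_d] = sum_i (1 - C(N - n_i, d) / C(N, d))` — the analytic expectation
#' that the resampling curve estimates.
#'
#' @param counts integer abundances of one sample.
#' @param depth subsampling depth.
#' @export
rarefaction_expected <- function(counts, depth) {
  check_counts(counts)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (depth > n) stop("depth exceeds the sample total")
  sum(1 - exp(lchoose(n - counts, depth) - lchoose(n, depth)))
}

#' Bray-Curtis distance matrix between samples
#'
#' `d(a, b) = sum |x_a - x_b| / sum (x_a + x_b)` on relative abundances
#' (each sample normalised to sum 1).
#'
#' @param x an [otu_table] (at least 2 samples, none all-zero).
#' @return symmetric sample x sample matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  tot <- colSums(x$abundance)
  if (any(tot == 0))
    stop("all-zero sample(s): ", paste(sample_ids(x)[tot == 0], collapse = ", "))
  rel <- sweep(x$abundance, 2, tot, "/")
  as.matrix(vegan::vegdist(t(rel), method = "bray"))
}

#' NMDS ordination with Kruskal stress
#'
#' Non-metric multidimensional scaling of a distance matrix (classical
#' scaling start, isotonic-regression refinement, random restarts as
#' provided by vegan's engine), seeded for reproducibility.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param k embedding dimension (default 2).
#' @param seed RNG seed for the restarts.
#' @param trymax maximum random restarts.
#' @return list with `points` (n x k coordinates) and `stress`
#'   (Kruskal stress-1, 0-1 scale).
#' @export
nmds_ordination <- function(d, k = 2, seed = 1, trymax = 20) {
  dd <- stats::as.dist(d)
  set.seed(seed)
  fit <- vegan::metaMDS(dd, k = k, trymax = trymax, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  list(points = fit$points, stress = fit$stress)
}
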