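#' Truncate a similarity matrix at a threshold
#'
#' Entries below the cutoff are set to zero, the diagonal to one, and OTUs
#' left without any off-diagonal entry at or above the cutoff are dropped.
#' The spectrum of this truncated matrix is what the RMT threshold scan
#' analyses.
#'
#' @param sim a `similarity_matrix` from [pearson_similarity()].
#' @param threshold similarity cutoff in (0, 1).
#' @return the truncated symmetric matrix over the active OTUs (possibly
#'   `0 x 0` when nothing survives).
#' @export
truncate_similarity <- function(sim, threshold) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (!(threshold > 0 && threshold < 1))
    stop("`threshold` must lie strictly between 0 and 1")
  a <- sim$values
  diag(a) <- 0
  a[a < threshold] <- 0
  active <- rowSums(a > 0) > 0
  a <- a[active, active, drop = FALSE]
  diag(a) <- 1
  a
}

#' Unfold eigenvalues to unit mean spacing
#'
#' Fits a smooth monotone approximation of the cumulative spectral function
#' (polynomial of `degree`, reduced automatically if the fit is
#' non-monotone over the data range), maps each eigenvalue through it, and
#' returns nearest-neighbour spacings normalised to unit mean. Exact
#' degeneracies are split by deterministic increments below 1e-10 so the
#' spectrum is simple. A small fraction of spacings at each spectral edge is
#' discarded (`trim`): polynomial unfolding is least reliable there and the
#' spacing statistics are a bulk property.
#'
#' @param eigenvalues numeric vector (at least 20 distinct values).
#' @param degree polynomial degree for the cumulative-spectral-function fit.
#' @param trim fraction of spacings dropped at each spectral edge.
#' @return numeric vector of unfolded spacings.
#' @export
unfold_eigenvalues <- function(eigenvalues, degree = 5, trim = 0.02) {
  ev <- sort(eigenvalues)
  if (length(unique(ev)) < 20)
    stop("need at least 20 distinct eigenvalues for a meaningful spacing distribution")
  dup <- duplicated(ev)
  if (any(dup)) {
    ev[dup] <- ev[dup] + cumsum(dup)[dup] * 1e-10
    ev <- sort(ev)
  }
  n <- length(ev)
  f_emp <- (seq_len(n) - 0.5) / n
  fh <- NULL
  for (deg in seq(degree, 1)) {
    fit <- stats::lm(f_emp ~ stats::poly(ev, deg, raw = TRUE))
    cand <- stats::fitted(fit)
    tol <- 1e-10 * diff(range(cand))   # monotone up to rounding
    if (all(diff(cand) > -tol)) { fh <- cummax(cand); break }
  }
  if (is.null(fh))
    stop("could not fit a monotone cumulative spectral function at any degree <= ",
         degree)
  s <- pmax(diff(n * fh), 0)
  s <- s / mean(s)        # enforce exactly unit mean spacing
  k <- floor(trim * n)
  if (k > 0) s <- s[(k + 1):(length(s) - k)]
  s
}

#' Goodness of fit of spacings to the Poisson and GOE laws
#'
#' Chi-square test of binned unfolded spacings against the Poisson spacing
#' law `exp(-s)` (uncorrelated eigenvalues; modular, system-free spectra)
#' and against the Wigner surmise `(pi/2) s exp(-pi s^2 / 4)` of the
#' Gaussian orthogonal ensemble (level repulsion; strongly coupled system).
#' Bins are equal-probability under the Poisson null; expected masses come
#' from the analytic CDFs; bins with expected count below 1 are merged and
#' the degrees of freedom adjusted.
#'
#' @param spacings unfolded spacings from [unfold_eigenvalues()].
#' @param n_bins number of bins before merging.
#' @return a list with `chi2_poisson`, `p_poisson`, `df_poisson`,
#'   `chi2_goe`, `p_goe`, `df_goe`, `n_spacings`.
#' @export
nnsd_gof <- function(spacings, n_bins = 20) {
  if (length(spacings) < n_bins)
    stop("fewer spacings than bins")
  edges <- -log(1 - seq(0, 1, length.out = n_bins + 1))
  edges[n_bins + 1] <- Inf
  obs <- as.vector(table(cut(spacings, edges, include.lowest = TRUE)))
  n <- length(spacings)
  one <- function(cdf) {
    e <- n * diff(cdf(edges))
    o <- obs
    while (any(e < 1) && length(e) > 2) {
      i <- which.min(e)
      j <- if (i == length(e)) i - 1L else i + 1L
      e[j] <- e[j] + e[i]; o[j] <- o[j] + o[i]
      e <- e[-i]; o <- o[-i]
    }
    chi2 <- sum((o - e)^2 / e)
    df <- length(e) - 1L
    list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE), df = df)
  }
  pois <- one(function(x) 1 - exp(-x))
  goe <- one(function(x) 1 - exp(-pi * x^2 / 4))
  list(chi2_poisson = pois$chi2, p_poisson = pois$p, df_poisson = pois$df,
       chi2_goe = goe$chi2, p_goe = goe$p, df_goe = goe$df,
       n_spacings = length(spacings))
}

#' Spacing analysis of one truncated similarity matrix
#'
#' @param sim a `similarity_matrix`.
#' @param threshold similarity cutoff.
#' @param degree,trim,n_bins passed to [unfold_eigenvalues()] / [nnsd_gof()].
#' @return a list (`spacing_analysis`) with the threshold, active node
#'   count, eigenvalues, spacings, and the chi-square results; `NULL` fields
#'   when fewer than 20 active nodes remain.
#' @export
spacing_analysis <- function(sim, threshold, degree = 5, trim = 0.02,
                             n_bins = 20) {
  a <- truncate_similarity(sim, threshold)
  out <- list(threshold = threshold, n_active_nodes = nrow(a),
              eigenvalues = NULL, spacings = NULL,
              chi2_poisson = NA_real_, p_poisson = NA_real_,
              chi2_goe = NA_real_, p_goe = NA_real_)
  if (nrow(a) < 20) return(structure(out, class = "spacing_analysis"))
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  if (length(unique(ev)) < 20) return(structure(out, class = "spacing_analysis"))
  s <- unfold_eigenvalues(ev, degree = degree, trim = trim)
  g <- nnsd_gof(s, n_bins = n_bins)
  out$eigenvalues <- ev
  out$spacings <- s
  out[names(g)] <- g
  structure(out, class = "spacing_analysis")
}

#' Scan similarity thresholds from the top by the RMT criterion
#'
#' Decreasing from `scan_from`, each cutoff's truncated similarity matrix is
#' spectrally unfolded and its nearest-neighbour spacing distribution tested
#' against the Poisson law. While the spacings fit Poisson (p > `alpha`) the
#' spectrum behaves as a collection of uncorrelated (modular) levels; the
#' scan stops at the first cutoff where the Poisson fit fails, and the
#' selected threshold is the smallest scanned cutoff that still fitted.
#'
#' @param sim a `similarity_matrix`.
#' @param scan_from,scan_to,step scan grid (downward; `scan_from > scan_to`).
#' @param alpha significance level for the Poisson fit.
#' @param degree,trim,n_bins spectral settings, see [unfold_eigenvalues()].
#' @return an object of class `threshold_scan`: a data.frame `table` with
#'   one row per scanned cutoff (threshold, n_nodes, p_poisson, p_goe) plus
#'   `selected_threshold` (NA when no cutoff fits) and `mode = "rmt_scan"`.
#' @export
scan_threshold <- function(sim, scan_from = 0.99, scan_to = 0.30, step = 0.01,
                           alpha = 0.05, degree = 5, trim = 0.02, n_bins = 20) {
  if (!(scan_from > scan_to)) stop("`scan_from` must exceed `scan_to`")
  if (step <= 0) stop("`step` must be positive")
  grid <- seq(scan_from, scan_to, by = -step)
  rows <- list()
  selected <- NA_real_
  for (th in grid) {
    an <- spacing_analysis(sim, th, degree = degree, trim = trim,
                           n_bins = n_bins)
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = th, n_nodes = an$n_active_nodes,
      p_poisson = an$p_poisson, p_goe = an$p_goe)
    if (!is.na(an$p_poisson)) {
      if (an$p_poisson > alpha) {
        selected <- th
      } else if (!is.na(selected)) {
        break                     # transition found: stop below the last fit
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (is.na(selected))
    warning("no scanned threshold fitted the Poisson spacing law; ",
            "selected_threshold is NA")
  structure(list(table = tab, selected_threshold = selected,
                 mode = "rmt_scan", alpha = alpha),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("RMT threshold scan (", nrow(x$table), " cutoffs)\n", sep = "")
  cat("selected threshold:",
      if (is.na(x$selected_threshold)) "none" else
        format(x$selected_threshold), "\n")
  invisible(x)
}
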