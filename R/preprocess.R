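#' Prevalence filter
#'
#' Keeps OTUs detected (non-zero) in at least `min_present` samples. The
#' default is the absolute majority, `floor(n/2) + 1` (8 of 15 samples for
#' the study design this pipeline mirrors); a fraction such as `0.75` is
#' resolved as `ceiling(fraction * n)`.
#'
#' @param x an [otu_table].
#' @param min_present integer count of samples, or a fraction in (0, 1);
#'   `NULL` means absolute majority.
#' @return the filtered [otu_table]; sample set and OTU order unchanged.
#' @export
prevalence_filter <- function(x, min_present = NULL) {
  stopifnot(inherits(x, "otu_table"))
  n <- n_samples(x)
  if (is.null(min_present)) {
    k <- floor(n / 2) + 1L
  } else if (min_present > 0 && min_present < 1) {
    k <- as.integer(ceiling(min_present * n))
  } else {
    k <- as.integer(min_present)
  }
  if (k < 1 || k > n)
    stop("`min_present` must resolve to an integer in 1..n_samples, got ", k)
  keep <- rowSums(x$abundance > 0) >= k
  if (!any(keep))
    stop("prevalence filter removed every OTU; lower `min_present` (was ", k, ")")
  otu_table(x$abundance[keep, , drop = FALSE],
            taxonomy = x$taxonomy, group = x$group)
}

#' Replace zero abundances by a small positive fill value
#'
#' After prevalence filtering, remaining blanks (zeros) are filled with a
#' small constant (0.01 by default) so that the log10 transform is defined
#' for every cell. Non-zero cells are untouched.
#'
#' @param x an [otu_table].
#' @param fill_value positive replacement for zero cells.
#' @return the filled [otu_table].
#' @export
fill_blanks <- function(x, fill_value = 0.01) {
  stopifnot(inherits(x, "otu_table"))
  if (fill_value <= 0)
    stop("`fill_value` must be > 0 (log10 downstream requires positivity)")
  ab <- x$abundance
  ab[ab == 0] <- fill_value
  otu_table(ab, taxonomy = x$taxonomy, group = x$group)
}

#' Elementwise log10 transform
#'
#' @param x an [otu_table] with strictly positive cells (see [fill_blanks()]).
#' @return the transformed [otu_table].
#' @export
log10_transform <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  if (any(x$abundance <= 0))
    stop("non-positive abundances present; run fill_blanks() first")
  otu_table(log10(x$abundance), taxonomy = x$taxonomy, group = x$group,
            log_scale = TRUE)
}

#' Pairwise similarity matrix between OTUs
#'
#' Absolute Pearson (default) correlation of OTU profiles across samples,
#' with the correlation sign recorded separately so that edge signs
#' (positive/negative association) survive the absolute-value transform.
#'
#' @param x an [otu_table] (normally filtered, filled and log10-transformed).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return an object of class `similarity_matrix` with fields `otu_ids`,
#'   `values` (symmetric, in \[0, 1\], unit diagonal) and `sign`.
#' @export
pearson_similarity <- function(x, method = c("pearson", "spearman")) {
  stopifnot(inherits(x, "otu_table"))
  method <- match.arg(method)
  if (n_samples(x) < 3)
    stop("need at least 3 samples to correlate")
  sds <- apply(x$abundance, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance OTU(s), cannot correlate a constant: ",
         paste(otu_ids(x)[sds == 0], collapse = ", "))
  r <- stats::cor(t(x$abundance), method = method)
  r <- (r + t(r)) / 2            # enforce exact symmetry
  v <- abs(r)
  diag(v) <- 1
  structure(list(otu_ids = otu_ids(x), values = v, sign = sign(r)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("Similarity matrix: %d OTUs; off-diagonal |r| median %.3f, max %.3f\n",
              length(x$otu_ids), stats::median(off), max(off)))
  invisible(x)
}
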