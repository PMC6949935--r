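#' Specification for a synthetic two-group community
#'
#' Describes the generative model used to validate the pipeline end to end:
#' two groups of samples (default 15 + 15, the design of the soil study this
#' package mirrors), a few hundred OTUs of which blocks form planted
#' correlation modules on the log-abundance scale, structural zeros from
#' latent thresholding, and environmental variables optionally driven by
#' specific modules and shifted between groups.
#'
#' @param n_samples_per_group samples per group (default 15).
#' @param n_otus total OTUs; those beyond the planted blocks are
#'   independent background OTUs.
#' @param module_sizes integer vector of planted block sizes (their sum
#'   must not exceed `n_otus`).
#' @param within_module_correlation latent Pearson correlation inside each
#'   block, in (0, 1).
#' @param between_module_correlation latent correlation between members of
#'   different blocks (default 0).
#' @param env_drivers named list mapping module id (as character) to
#'   `list(variable =, strength =)`: the variable is generated as the
#'   module's mean latent profile scaled by `strength` plus noise.
#' @param group_shift named numeric vector of between-group mean shifts (in
#'   sd units) added to the second group's environmental variables.
#' @param zero_inflation fraction of cells set to zero by thresholding the
#'   smallest latent values, in \[0, 1).
#' @param dispersion sd of log10 abundance (> 0).
#' @param mu_log mean of log10 abundance.
#' @param env_variables names of the environmental variables to generate.
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @return a validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_samples_per_group = 15,
                       n_otus = 200,
                       module_sizes = rep(25L, 4),
                       within_module_correlation = 0.9,
                       between_module_correlation = 0,
                       env_drivers = list(
                         `1` = list(variable = "T", strength = 0.7),
                         `2` = list(variable = "pH", strength = 0.7)),
                       group_shift = c(T = 2, pH = 1.2, AN = -2),
                       zero_inflation = 0.2,
                       dispersion = 1,
                       mu_log = 2,
                       env_variables = c("W", "T", "pH", "EC", "OM",
                                         "AP", "AK", "NN", "AN"),
                       seed = 1) {
  if (sum(module_sizes) > n_otus)
    stop("module sizes sum to more than `n_otus`")
  if (!(within_module_correlation > 0 && within_module_correlation < 1))
    stop("`within_module_correlation` must lie in (0, 1)")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("`zero_inflation` must lie in [0, 1)")
  if (dispersion <= 0) stop("`dispersion` must be positive")
  for (m in names(env_drivers))
    if (!env_drivers[[m]]$variable %in% env_variables)
      stop("env driver for module ", m, " names an unknown variable")
  structure(list(n_samples_per_group = n_samples_per_group, n_otus = n_otus,
                 module_sizes = as.integer(module_sizes),
                 within_module_correlation = within_module_correlation,
                 between_module_correlation = between_module_correlation,
                 env_drivers = env_drivers, group_shift = group_shift,
                 zero_inflation = zero_inflation, dispersion = dispersion,
                 mu_log = mu_log, env_variables = env_variables, seed = seed),
            class = "synth_spec")
}

planted_sigma <- function(spec) {
  p <- spec$n_otus
  blocks <- rep(seq_along(spec$module_sizes), spec$module_sizes)
  blocks <- c(blocks, rep(0L, p - length(blocks)))
  sig <- diag(p)
  planted <- blocks > 0
  if (spec$between_module_correlation != 0)
    sig[planted, planted] <- spec$between_module_correlation
  for (m in seq_along(spec$module_sizes)) {
    idx <- which(blocks == m)
    sig[idx, idx] <- spec$within_module_correlation
  }
  diag(sig) <- 1
  list(sigma = sig, blocks = blocks)
}

#' Generate a synthetic two-group community with planted modules
#'
#' Log10 abundances are correlated Gaussian latent variables (log-normal
#' counts) with the planted block structure drawn independently per group;
#' structural zeros come from thresholding the globally smallest latent
#' values at rate `zero_inflation`; each driven environmental variable is
#' the driving module's mean latent profile scaled by its strength plus
#' independent noise, and group shifts are added afterwards.
#'
#' @param spec a [synth_spec()].
#' @return list with `otu` (an [otu_table] with taxonomy and LC/CLC-style
#'   group labels), `metadata` (a [sample_metadata]), and `truth` (planted
#'   partition, driver map, seed).
#' @export
generate_community <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  ps <- planted_sigma(spec)
  ch <- tryCatch(chol(ps$sigma), error = function(e)
    stop("planted correlation structure is not positive semi-definite ",
         "(within = ", spec$within_module_correlation,
         ", between = ", spec$between_module_correlation, ")"))
  n <- spec$n_samples_per_group
  p <- spec$n_otus
  z <- matrix(stats::rnorm(2 * n * p), nrow = 2 * n) %*% ch
  groups <- rep(c("LC", "CLC"), each = n)
  samples <- c(paste0("LC", seq_len(n)), paste0("CLC", seq_len(n)))
  otus <- paste0("OTU", seq_len(p))
  dimnames(z) <- list(samples, otus)

  ab <- 10^(spec$mu_log + spec$dispersion * z)
  if (spec$zero_inflation > 0) {
    thr <- stats::quantile(z, spec$zero_inflation)
    ab[z <= thr] <- 0
  }

  phyla <- c("Proteobacteria", "Actinobacteria", "Chloroflexi",
             "Acidobacteria", "Bacteroidetes", "Gemmatimonadetes",
             "Planctomycetes", "Firmicutes")
  taxonomy <- stats::setNames(
    paste0("k__Bacteria;p__", sample(phyla, p, replace = TRUE), ";c__;o__"),
    otus)

  vars <- as.data.frame(matrix(stats::rnorm(2 * n * length(spec$env_variables)),
                               nrow = 2 * n,
                               dimnames = list(samples, spec$env_variables)))
  for (m in names(spec$env_drivers)) {
    drv <- spec$env_drivers[[m]]
    idx <- which(ps$blocks == as.integer(m))
    if (!length(idx)) next
    latent <- as.numeric(scale(rowMeans(z[, idx, drop = FALSE])))
    vars[[drv$variable]] <- drv$strength * latent +
      sqrt(1 - drv$strength^2) * stats::rnorm(2 * n)
  }
  for (v in names(spec$group_shift))
    if (v %in% names(vars))
      vars[[v]] <- vars[[v]] + spec$group_shift[[v]] * (groups == "CLC")

  group <- stats::setNames(groups, samples)
  list(otu = otu_table(t(ab), taxonomy = taxonomy, group = group),
       metadata = sample_metadata(vars, group = group),
       truth = list(partition = stats::setNames(ps$blocks, otus),
                    drivers = spec$env_drivers,
                    seed = spec$seed))
}

#' Generate a community of fully independent OTUs
#'
#' Diagonal latent covariance; the null control for false-positive and
#' spacing-statistics calibration.
#'
#' @param n_otus,n_samples dimensions (at least 3 samples; correlation is
#'   degenerate below that).
#' @param seed RNG seed.
#' @param mu_log,dispersion log10-abundance location and sd.
#' @return an [otu_table].
#' @export
generate_null_community <- function(n_otus, n_samples, seed = 1,
                                    mu_log = 2, dispersion = 1) {
  if (n_samples < 3)
    stop("need at least 3 samples (pairwise correlation is degenerate)")
  set.seed(seed)
  z <- matrix(stats::rnorm(n_samples * n_otus), nrow = n_samples)
  ab <- t(10^(mu_log + dispersion * z))
  dimnames(ab) <- list(paste0("OTU", seq_len(n_otus)),
                       paste0("S", seq_len(n_samples)))
  otu_table(ab)
}
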