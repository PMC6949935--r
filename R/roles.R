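#' Within-module connectivity (Zi)
#'
#' For node i in module s, `Zi = (k_is - mean_s) / sd_s`, where `k_is` is
#' the number of links from i into its own module and mean/sd are taken over
#' the members of s (population standard deviation, the convention of the
#' Guimera-Amaral role taxonomy the thresholds derive from). Modules whose
#' members all have the same within-module degree (sd = 0, including
#' singletons) give Zi = 0: all members are topologically equivalent and
#' none is a hub.
#'
#' @param net an `eco_network`.
#' @param partition a `module_partition` covering all nodes.
#' @return named numeric vector over nodes.
#' @export
compute_zi <- function(net, partition) {
  memb <- partition$membership[net$nodes]
  if (any(is.na(memb))) stop("partition does not cover all network nodes")
  kin <- within_module_degree(net, memb)
  z <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  for (m in unique(memb)) {
    idx <- names(memb)[memb == m]
    k <- kin[idx]
    mu <- mean(k)
    sd_pop <- sqrt(mean((k - mu)^2))
    z[idx] <- if (sd_pop > 0) (k - mu) / sd_pop else 0
  }
  z
}

# links from each node into its own module
within_module_degree <- function(net, memb) {
  k <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  same <- memb[net$edges$source] == memb[net$edges$target]
  for (e in which(same)) {
    k[net$edges$source[e]] <- k[net$edges$source[e]] + 1
    k[net$edges$target[e]] <- k[net$edges$target[e]] + 1
  }
  k
}

#' Among-module connectivity (Pi, participation coefficient)
#'
#' `Pi = 1 - sum_t (k_it / k_i)^2` over the modules t the node links to.
#' Zero when every neighbour shares the node's module; approaches 1 when
#' links spread evenly over many modules.
#'
#' @inheritParams compute_zi
#' @return named numeric vector over nodes, values in \[0, 1).
#' @export
compute_pi <- function(net, partition) {
  memb <- partition$membership[net$nodes]
  if (any(is.na(memb))) stop("partition does not cover all network nodes")
  p <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  nbr_modules <- c(stats::setNames(memb[net$edges$target], net$edges$source),
                   stats::setNames(memb[net$edges$source], net$edges$target))
  by_node <- split(unname(nbr_modules), names(nbr_modules))
  for (v in names(by_node)) {
    k <- length(by_node[[v]])
    p[v] <- 1 - sum((table(by_node[[v]]) / k)^2)
  }
  p
}

#' Classify nodes into topological roles
#'
#' The four-way rule of the Zi-Pi plane: network hubs (`Zi > 2.5` and
#' `Pi > 0.62`), module hubs (`Zi > 2.5`, `Pi <= 0.62`), connectors
#' (`Zi <= 2.5`, `Pi > 0.62`) and peripherals. Boundary values fall in the
#' `<=` branches.
#'
#' @param zi,pi named numeric vectors as returned by [compute_zi()] /
#'   [compute_pi()].
#' @return named character vector of roles.
#' @export
classify_roles <- function(zi, pi) {
  stopifnot(identical(names(zi), names(pi)))
  role <- ifelse(zi > 2.5,
                 ifelse(pi > 0.62, "network_hub", "module_hub"),
                 ifelse(pi > 0.62, "connector", "peripheral"))
  stats::setNames(role, names(zi))
}

#' Node-role table for the Zi-Pi scatter
#'
#' One row per node with Zi, Pi, role, module and phylum — the table behind
#' the standard Z-p plot.
#'
#' @param net an `eco_network`.
#' @param partition a `module_partition`.
#' @param taxonomy optional named lineage vector (phylum extracted via
#'   [parse_phylum()]).
#' @return data.frame with columns node, module, zi, pi, role, phylum; role
#'   counts are attached as attribute `"role_counts"`.
#' @export
zp_table <- function(net, partition, taxonomy = NULL) {
  zi <- compute_zi(net, partition)
  pi_ <- compute_pi(net, partition)
  role <- classify_roles(zi, pi_)
  phylum <- if (!is.null(taxonomy)) parse_phylum(taxonomy[net$nodes])
            else rep(NA_character_, length(net$nodes))
  out <- data.frame(node = net$nodes,
                    module = unname(partition$membership[net$nodes]),
                    zi = unname(zi[net$nodes]),
                    pi = unname(pi_[net$nodes]),
                    role = unname(role[net$nodes]),
                    phylum = phylum,
                    stringsAsFactors = FALSE)
  counts <- table(factor(out$role, levels = c("peripheral", "connector",
                                              "module_hub", "network_hub")))
  attr(out, "role_counts") <- counts
  out
}
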