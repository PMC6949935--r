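#' Run the full per-group analysis and write a report bundle
#'
#' Splits the samples by group label, fits [mena()] independently per group
#' (the two groups are never pooled into one network), and writes the
#' complete report bundle: a side-by-side topology panel, per-group role
#' tables, module-environment tables, Mantel tables, an alpha-diversity
#' table, network exports (edge list and GraphML), the group t-test table,
#' and a run log recording the seed and every configuration value.
#'
#' @param otu an [otu_table] with group labels, or a path to one.
#' @param metadata a [sample_metadata], or a path to one; optional.
#' @param out_dir output directory (created if needed).
#' @param truth optional planted-truth list from [generate_community()];
#'   written as a JSON sidecar for test harnesses.
#' @param ... passed to [mena()] (threshold, seed, ...).
#' @return invisibly, a named list of the per-group `mena` fits.
#' @export
run_pipeline <- function(otu, metadata = NULL, out_dir, truth = NULL, ...) {
  if (is.character(otu)) otu <- read_otu_table(otu)
  if (is.character(metadata)) metadata <- read_metadata(metadata, otu)
  if (is.null(otu$group) && !is.null(metadata) && !is.null(metadata$group)) {
    otu$group <- metadata$group[sample_ids(otu)]
    names(otu$group) <- sample_ids(otu)
  }
  if (is.null(otu$group)) stop("no group labels; run_pipeline is per-group")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- unique(stats::na.omit(otu$group))
  dots <- list(...)

  fits <- list()
  for (g in groups) {
    keep <- names(otu$group)[otu$group == g]
    sub_otu <- otu_table(otu$abundance[, keep, drop = FALSE],
                         taxonomy = otu$taxonomy,
                         group = otu$group[keep])
    sub_meta <- NULL
    if (!is.null(metadata))
      sub_meta <- sample_metadata(
        metadata$variables[keep, , drop = FALSE],
        group = metadata$group[keep])
    fits[[g]] <- do.call(mena, c(list(otu = sub_otu, metadata = sub_meta),
                                 dots))
  }

  panel <- do.call(cbind, lapply(fits, function(f) t(f$topology)))
  colnames(panel) <- groups
  utils::write.table(data.frame(property = rownames(panel), panel,
                                check.names = FALSE),
                     file.path(out_dir, "topology_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  for (g in groups) {
    f <- fits[[g]]
    utils::write.table(f$roles, file.path(out_dir, paste0("roles_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(f$network, file.path(out_dir, paste0("network_", g, ".tsv")),
                  "edgelist", partition = f$partition)
    write_network(f$network,
                  file.path(out_dir, paste0("network_", g, ".graphml")),
                  "graphml", partition = f$partition)
    if (!is.null(f$env_cor))
      utils::write.table(f$env_cor,
                         file.path(out_dir, paste0("module_env_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(f$mantel))
      utils::write.table(f$mantel,
                         file.path(out_dir, paste0("mantel_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(f$hierarchy))
      writeLines(f$hierarchy$newick,
                 file.path(out_dir, paste0("eigengene_tree_", g, ".nwk")))
  }

  is_counts <- all(otu$abundance == round(otu$abundance))
  if (is_counts) {
    div <- alpha_diversity(otu)
    div$group <- unname(otu$group[div$sample])
    utils::write.table(div, file.path(out_dir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(metadata) && !is.null(metadata$group) &&
      length(unique(stats::na.omit(metadata$group))) == 2)
    utils::write.table(group_ttests(metadata),
                       file.path(out_dir, "group_ttests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(out_dir, "planted_truth.json"),
                         auto_unbox = TRUE, digits = NA)

  cfg <- fits[[1]]$config
  log_lines <- c(
    paste0("groups: ", paste(groups, collapse = ", ")),
    paste0("threshold_mode: ", fits[[1]]$threshold_mode),
    paste0("threshold: ", vapply(fits, function(f) format(f$threshold),
                                 character(1)), " (", groups, ")"),
    paste0("seed: ", cfg$seed),
    paste0(names(cfg), ": ", vapply(cfg, function(v)
      paste(format(v), collapse = ","), character(1))))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(fits)
}
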