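#' Construct an OTU abundance table
#'
#' The basic container of the pipeline: an OTU-by-sample matrix of
#' non-negative abundances (counts or relative abundances), with optional
#' taxonomy lineage strings per OTU and an optional group label per sample.
#'
#' @param abundance numeric matrix, rows = OTUs, columns = samples. Must have
#'   unique, non-empty row and column names.
#' @param taxonomy optional named character vector mapping OTU id to a
#'   lineage string (e.g. `"k__Bacteria;p__Chloroflexi;..."`).
#' @param group optional named character vector mapping sample id to a group
#'   label (e.g. `"LC"` / `"CLC"`).
#' @param log_scale set by [log10_transform()]: marks the table as holding
#'   log10 abundances, for which negative cells are legitimate.
#' @return an object of class `otu_table`.
#' @examples
#' m <- matrix(c(5, 0, 2, 1, 3, 4), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
#' otu_table(m)
#' @export
otu_table <- function(abundance, taxonomy = NULL, group = NULL,
                      log_scale = FALSE) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("`abundance` must be a numeric matrix")
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("`abundance` must carry OTU ids as rownames and sample ids as colnames")
  dup_o <- unique(rownames(abundance)[duplicated(rownames(abundance))])
  if (length(dup_o))
    stop("duplicate OTU ids: ", paste(dup_o, collapse = ", "))
  dup_s <- unique(colnames(abundance)[duplicated(colnames(abundance))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (ncol(abundance) < 2)
    stop("need at least 2 samples")
  if (any(!is.finite(abundance)))
    stop("abundance values must be finite")
  if (!log_scale && any(abundance < 0)) {
    bad <- which(abundance < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at OTU '%s', sample '%s'",
                 rownames(abundance)[bad[1]], colnames(abundance)[bad[2]]))
  }
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[intersect(names(taxonomy), rownames(abundance))]
    storage.mode(taxonomy) <- "character"
  }
  if (!is.null(group)) {
    group <- group[colnames(abundance)]
    names(group) <- colnames(abundance)
  }
  structure(list(abundance = abundance, taxonomy = taxonomy, group = group,
                 log_scale = log_scale),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy for %d OTUs\n", length(x$taxonomy)))
  if (!is.null(x$group))
    cat("  groups:", paste(names(table(x$group)), table(x$group),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$abundance)

n_samples <- function(x) ncol(x$abundance)
otu_ids <- function(x) rownames(x$abundance)
sample_ids <- function(x) colnames(x$abundance)

detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read an OTU table from a delimited text file
#'
#' Expects OTU ids in the first column and sample ids in the header row; a
#' final column named `taxonomy` (case-insensitive) is split off into the
#' taxonomy map. Tab-delimited is the canonical dialect; comma is
#' auto-detected from the header line.
#'
#' @param path path to the file.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- detect_sep(path)
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]][-1]
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup))
    stop("duplicate sample ids in header: ", paste(dup, collapse = ", "))
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate OTU ids: ", paste(dup, collapse = ", "))
  df <- df[, -1, drop = FALSE]
  taxonomy <- NULL
  tax_col <- which(tolower(names(df)) == "taxonomy")
  if (length(tax_col)) {
    taxonomy <- stats::setNames(df[[tax_col[1]]], ids)
    df <- df[, -tax_col, drop = FALSE]
  }
  mat <- matrix(NA_real_, nrow = length(ids), ncol = ncol(df),
                dimnames = list(ids, names(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & nzchar(df[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric abundance at OTU '%s', sample '%s': '%s'",
                   ids[bad[1]], names(df)[j], df[[j]][bad[1]]))
    neg <- which(v < 0)
    if (length(neg))
      stop(sprintf("negative abundance at OTU '%s', sample '%s'",
                   ids[neg[1]], names(df)[j]))
    mat[, j] <- v
  }
  if (any(is.na(mat)))
    stop("missing abundance cells are not allowed in an OTU table")
  otu_table(mat, taxonomy = taxonomy)
}

#' Write an OTU table to a tab-delimited file
#'
#' Inverse of [read_otu_table()]: OTU ids in the first column (`#OTU_ID`),
#' one column per sample, optional trailing `taxonomy` column.
#'
#' @param x an [otu_table].
#' @param path output path.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(`#OTU_ID` = otu_ids(x), x$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy))
    df$taxonomy <- unname(x$taxonomy[otu_ids(x)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the phylum from a greengenes-style lineage string
#'
#' Greedy `p__` prefix rule; anything unparseable maps to `"Unclassified"`,
#' so the function is total (network plots colour nodes by phylum and need a
#' label for every node).
#'
#' @param lineage character vector of lineage strings.
#' @return character vector of phylum names.
#' @examples
#' parse_phylum("k__Bacteria;p__Chloroflexi;c__Anaerolineae")
#' @export
parse_phylum <- function(lineage) {
  lineage <- ifelse(is.na(lineage), "", as.character(lineage))
  out <- rep("Unclassified", length(lineage))
  m <- regexpr("p__[^;]*", lineage)
  has <- which(m > 0)
  val <- trimws(sub("^p__", "", regmatches(lineage, m)))
  out[has[nzchar(val)]] <- val[nzchar(val)]
  out
}
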