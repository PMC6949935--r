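#' Construct a sample metadata table
#'
#' Environmental variables measured per sample (in the soil study: moisture
#' W, temperature T, pH, electrical conductivity EC, organic matter OM,
#' available P and K, nitrate and ammonium N), plus an optional group label.
#' Missing values stay `NA`; they are never silently replaced by zero and are
#' excluded pairwise in downstream correlations.
#'
#' @param variables data.frame of numeric variables, rownames = sample ids.
#' @param group optional named character vector of group labels per sample.
#' @param units optional named character vector of unit strings per variable.
#' @return an object of class `sample_metadata`.
#' @export
sample_metadata <- function(variables, group = NULL, units = NULL) {
  if (!is.data.frame(variables)) stop("`variables` must be a data.frame")
  if (is.null(rownames(variables))) stop("`variables` needs sample ids as rownames")
  ids <- rownames(variables)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  if (!all(vapply(variables, is.numeric, logical(1))))
    stop("all metadata variables must be numeric (group labels go in `group`)")
  if (!is.null(group)) {
    group <- group[ids]
    names(group) <- ids
  }
  structure(list(sample_ids = ids, variables = variables,
                 group = group, units = units),
            class = "sample_metadata")
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("Sample metadata: %d samples x %d variables (%s)\n",
              length(x$sample_ids), ncol(x$variables),
              paste(names(x$variables), collapse = ", ")))
  invisible(x)
}

#' Read sample metadata from a delimited text file
#'
#' Sample ids in the first column; non-numeric columns are treated as group
#' labels (the first one becomes `$group`). Blank cells become `NA`, never 0.
#'
#' @param path path to the file.
#' @param otu optional [otu_table]; if given, the sample sets must match
#'   exactly and an error lists the symmetric difference otherwise.
#' @return a [sample_metadata].
#' @export
read_metadata <- function(path, otu = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = c("", "NA"))
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  numeric_ok <- vapply(df, function(v)
    is.numeric(v) || all(is.na(v) | !is.na(suppressWarnings(as.numeric(v)))),
    logical(1))
  group <- NULL
  if (any(!numeric_ok)) {
    gcol <- which(!numeric_ok)[1]
    group <- stats::setNames(as.character(df[[gcol]]), ids)
    df <- df[, numeric_ok, drop = FALSE]
  }
  vars <- as.data.frame(lapply(df, function(v) suppressWarnings(as.numeric(v))),
                        check.names = FALSE)
  rownames(vars) <- ids
  if (!is.null(otu)) {
    missing_in_meta <- setdiff(sample_ids(otu), ids)
    extra_in_meta <- setdiff(ids, sample_ids(otu))
    if (length(missing_in_meta) || length(extra_in_meta))
      stop("sample sets differ between OTU table and metadata; ",
           "missing from metadata: [",
           paste(missing_in_meta, collapse = ", "),
           "]; absent from OTU table: [",
           paste(extra_in_meta, collapse = ", "), "]")
    vars <- vars[sample_ids(otu), , drop = FALSE]
    ids <- sample_ids(otu)
    if (!is.null(group)) group <- group[ids]
  }
  sample_metadata(vars, group = group)
}

#' Write sample metadata to a tab-delimited file
#'
#' @param x a [sample_metadata].
#' @param path output path.
#' @export
write_metadata <- function(x, path) {
  df <- data.frame(sample = x$sample_ids, check.names = FALSE)
  if (!is.null(x$group)) df$group <- unname(x$group[x$sample_ids])
  df <- cbind(df, x$variables)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
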