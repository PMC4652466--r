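#' Abundance matrix container
#'
#' An `abundance_matrix` holds a samples x OTUs table of non-negative integer
#' read counts together with a sample -> study-group mapping. Rows are
#' samples, columns are OTUs; OTU labels are unique (duplicate taxon names
#' are disambiguated on read with an appended integer).
#'
#' @param counts integer matrix, samples in rows, OTUs in columns. Must have
#'   rownames (sample IDs) and colnames (OTU labels).
#' @param groups named character vector mapping sample ID to group label, or
#'   `NULL` when no group metadata is available.
#' @return An object of class `abundance_matrix` with elements `counts`
#'   (integer matrix), `sample_ids`, `otu_ids` and `groups`.
#' @export
abundance_matrix <- function(counts, groups = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and OTU colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU labels after disambiguation: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (!is.null(groups)) {
    groups <- vapply(groups, as.character, character(1))
    missing <- setdiff(rownames(counts), names(groups))
    if (length(missing))
      warning("samples absent from metadata: ", paste(missing, collapse = ", "))
    groups <- groups[intersect(names(groups), rownames(counts))]
  }
  structure(
    list(counts = counts,
         sample_ids = rownames(counts),
         otu_ids = colnames(counts),
         groups = groups),
    class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$counts)

# Deterministic disambiguation of duplicated OTU labels: first-appearance
# order, suffix starts at 1 and is only applied to labels that collide.
disambiguate_labels <- function(labels) {
  dup <- labels[duplicated(labels)]
  if (!length(dup)) return(labels)
  out <- labels
  for (lab in unique(dup)) {
    idx <- which(labels == lab)
    out[idx] <- paste0(lab, "_", seq_along(idx))
  }
  out
}

#' Read an abundance table plus sample metadata
#'
#' Reads a delimited count table (header row = OTU labels, first column =
#' sample IDs; samples in rows by default) and a two-column metadata table
#' (`sample_id`, `group`). Duplicate OTU labels are disambiguated by
#' appending `_1`, `_2`, ... in order of first appearance.
#'
#' @param path path to the abundance table.
#' @param metadata_path optional path to the metadata table.
#' @param sep field delimiter; tab by default, use `","` for CSV.
#' @param transpose set `TRUE` when the file stores OTUs as rows.
#' @return an [abundance_matrix].
#' @export
read_abundance_table <- function(path, metadata_path = NULL, sep = "\t",
                                 transpose = FALSE) {
  if (!file.exists(path)) stop("abundance table not found: ", path)
  # header parsed by hand: read.table would uniquify duplicated OTU labels
  # with make.unique, hiding the collisions we must disambiguate ourselves
  header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  if (length(header) < 2) stop("abundance table needs an ID column and >=1 OTU")
  raw <- utils::read.table(path, sep = sep, header = FALSE, skip = 1,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) != length(header))
    stop("header and data rows disagree on column count")
  ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  colnames(mat) <- header[-1]
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric count '%s' at row '%s', column '%s'",
                 mat[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(mat)[bad[1, 2]]))
  }
  dimnames(num) <- list(ids, disambiguate_labels(colnames(mat)))
  if (transpose) num <- t(num)
  if (anyDuplicated(rownames(num)))
    stop("duplicate sample ID in table: ",
         paste(unique(rownames(num)[duplicated(rownames(num))]),
               collapse = ", "))
  groups <- NULL
  if (!is.null(metadata_path)) groups <- read_group_metadata(metadata_path, sep)
  abundance_matrix(num, groups)
}

#' Read sample metadata
#'
#' @param path delimited file with columns `sample_id` and `group`.
#' @param sep field delimiter.
#' @return named character vector: group label per sample ID.
#' @export
read_group_metadata <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ID in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  stats::setNames(as.character(md$group), as.character(md$sample_id))
}

#' Write an abundance table (and optionally metadata) back to disk
#'
#' @param m an [abundance_matrix].
#' @param path output path for the count table.
#' @param metadata_path optional output path for `sample_id`/`group` metadata.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(m, path, metadata_path = NULL, sep = "\t") {
  df <- data.frame(sample_id = m$sample_ids, m$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    if (is.null(m$groups)) stop("matrix carries no group metadata")
    utils::write.table(
      data.frame(sample_id = names(m$groups), group = unname(m$groups)),
      metadata_path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Restrict an abundance matrix to one study group
#'
#' Keeps the samples belonging to `group`; OTU columns are untouched
#' (per-group OTU filtering happens in [filter_otus()]).
#'
#' @param m an [abundance_matrix] with group metadata.
#' @param group group label to keep.
#' @return an [abundance_matrix] over the group's samples.
#' @export
subset_group <- function(m, group) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (is.null(m$groups)) stop("matrix carries no group metadata")
  if (!group %in% m$groups)
    stop("unknown group '", group, "'; available: ",
         paste(sort(unique(m$groups)), collapse = ", "))
  keep <- m$sample_ids[m$sample_ids %in% names(m$groups)[m$groups == group]]
  abundance_matrix(m$counts[keep, , drop = FALSE], m$groups[keep])
}
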