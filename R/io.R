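#' Validate a raw count matrix
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   unique dimnames.
#' @return The matrix (integer storage), invisibly.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (anyNA(counts)) {
    idx <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN/NA count for gene %s, sample %s",
                 rownames(counts)[idx[1]], colnames(counts)[idx[2]]))
  }
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count for gene %s, sample %s",
                 rownames(counts)[idx[1]], colnames(counts)[idx[2]]))
  }
  if (any(counts != round(counts))) {
    stop("counts must be integers")
  }
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read a genes-by-samples count matrix
#'
#' Two plain-text layouts are supported: a TSV with gene rows, sample columns
#' and a header row of sample ids; or MatrixMarket (\code{.mtx}) with
#' one-id-per-line sidecar files \code{<stem>.genes.txt} and
#' \code{<stem>.samples.txt}.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"mtx"}; guessed from the extension by
#'   default.
#' @return Validated integer matrix (genes x samples).
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L) stop("malformed header: expected gene column plus sample columns")
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, comment.char = "")
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- as.character(df[[1]])
  } else {
    stem <- sub("\\.mtx$", "", path)
    gene_file <- paste0(stem, ".genes.txt")
    sample_file <- paste0(stem, ".samples.txt")
    if (!file.exists(gene_file) || !file.exists(sample_file)) {
      stop("mtx sidecar index files missing: ", gene_file, " / ", sample_file)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(gene_file)
    colnames(m) <- readLines(sample_file)
    counts <- m
  }
  if (!is.numeric(counts)) stop("non-numeric entries in count matrix")
  counts <- validate_counts(counts)
  counts
}

#' Write a count matrix
#'
#' @param counts genes x samples matrix.
#' @param path output path; \code{.mtx} selects MatrixMarket with sidecars.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path) {
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(stem, ".genes.txt"))
    writeLines(colnames(counts), paste0(stem, ".samples.txt"))
  } else {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read sample annotations
#'
#' TSV with columns \code{sample_id}, \code{clinical_group},
#' \code{autoantibody_subgroup} (empty string for none). Each row is
#' validated against the hierarchy and the per-group sample counts are
#' reported with \code{message()}.
#'
#' @param path file path.
#' @param hierarchy a \code{\link{myositis_hierarchy}}.
#' @param quiet suppress the group-size summary message.
#' @return data.frame of validated annotations (subgroup NA when absent).
#' @export
read_annotations <- function(path, hierarchy = myositis_hierarchy(), quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  ann <- validate_annotations(df, hierarchy)
  if (!quiet) {
    sizes <- table(ann$clinical_group)
    message("read ", nrow(ann), " samples: ",
            paste(names(sizes), as.integer(sizes), sep = "=", collapse = ", "))
  }
  ann
}

#' Write sample annotations
#'
#' @param annotations annotation data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations[, c("sample_id", "clinical_group", "autoantibody_subgroup")]
  out$autoantibody_subgroup[is.na(out$autoantibody_subgroup)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write grouped gene sets as a tidy table
#'
#' Serializes a \code{\link{group_gene_sets}} object (or any list of
#' per-group over/under sets) as TSV with columns \code{group},
#' \code{direction}, \code{rank}, \code{gene}; rank preserves the stored
#' (ascending q) order.
#'
#' @param sets a \code{group_gene_sets} object.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_gene_set_table <- function(sets, path) {
  rows <- list()
  for (g in names(sets)) {
    for (dir in c("over", "under")) {
      genes <- sets[[g]][[dir]]
      if (length(genes)) {
        rows[[paste(g, dir)]] <- data.frame(
          group = g, direction = dir, rank = seq_along(genes), gene = genes,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(group = character(), direction = character(),
               rank = integer(), gene = character())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set table written by \code{write_gene_set_table}
#'
#' @param path TSV path.
#' @param groups optional group order for the result (defaults to order of
#'   appearance).
#' @return A \code{group_gene_sets} object.
#' @export
read_gene_set_table <- function(path, groups = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  group_gene_sets_from_df(df, groups = groups)
}

#' Construct a group_gene_sets container
#'
#' A \code{group_gene_sets} object is a named list, one entry per group,
#' each a list with ordered character vectors \code{over} and \code{under}
#' (ascending q-value versus all samples). Over and under sets must be
#' disjoint within a group.
#'
#' @param sets named list of \code{list(over=, under=)} entries.
#' @return The validated, classed object.
#' @export
group_gene_sets <- function(sets) {
  for (g in names(sets)) {
    sets[[g]]$over <- as.character(sets[[g]]$over %||% character())
    sets[[g]]$under <- as.character(sets[[g]]$under %||% character())
    if (anyDuplicated(sets[[g]]$over) || anyDuplicated(sets[[g]]$under)) {
      stop("duplicate genes within a set for group ", g)
    }
    if (length(intersect(sets[[g]]$over, sets[[g]]$under))) {
      stop("over and under sets overlap for group ", g)
    }
  }
  structure(sets, class = "group_gene_sets")
}

group_gene_sets_from_df <- function(df, groups = NULL) {
  if (is.null(groups)) groups <- unique(df$group)
  sets <- lapply(groups, function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    list(
      over = sub$gene[sub$direction == "over"][order(sub$rank[sub$direction == "over"])],
      under = sub$gene[sub$direction == "under"][order(sub$rank[sub$direction == "under"])]
    )
  })
  names(sets) <- groups
  group_gene_sets(sets)
}

#' @export
print.group_gene_sets <- function(x, ...) {
  cat("Gene sets for", length(x), "groups\n")
  for (g in names(x)) {
    cat(sprintf("  %-7s over: %3d  under: %3d\n", g,
                length(x[[g]]$over), length(x[[g]]$under)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
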