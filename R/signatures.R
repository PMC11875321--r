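#' Top differentially overexpressed genes for a group
#'
#' The first \code{k} genes of the group's overexpressed set in ascending
#' order of q-value versus all samples (all of them when fewer than k).
#'
#' @param sets a \code{\link{group_gene_sets}}.
#' @param group group label present in \code{sets}.
#' @param k number of genes (default 15).
#' @return Character vector of length \code{min(k, |over set|)}.
#' @export
top_genes <- function(sets, group, k = 15L) {
  if (!group %in% names(sets)) stop("no sets for group ", group)
  over <- sets[[group]]$over
  if (!length(over)) warning("group ", group, " has an empty overexpressed set")
  utils::head(over, k)
}

#' Marker-vs-gene correlation matrix for one group
#'
#' Correlates, across the group's samples only (by default), each marker
#' gene with each listed gene. Constant expression vectors yield NA (an
#' explicit missing code), never 0.
#'
#' @param log_expr genes x samples log-expression matrix.
#' @param annotations validated sample annotations.
#' @param group group whose samples are used.
#' @param gene_list columns of the result (e.g. from \code{\link{top_genes}},
#'   already in ascending-q order).
#' @param markers named list of marker panels (default
#'   \code{\link{marker_sets}}); rows follow the flattened panel order.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param hierarchy a \code{\link{myositis_hierarchy}}.
#' @param all_samples correlate across every sample instead of the group's
#'   own (default FALSE).
#' @return markers x genes matrix of class \code{correlation_matrix} with
#'   attributes \code{group}, \code{method}, \code{n_samples}.
#' @export
marker_correlation <- function(log_expr, annotations, group, gene_list,
                               markers = marker_sets(),
                               method = c("pearson", "spearman"),
                               hierarchy = myositis_hierarchy(),
                               all_samples = FALSE) {
  method <- match.arg(method)
  marker_genes <- unlist(markers, use.names = FALSE)
  missing <- setdiff(c(marker_genes, gene_list), rownames(log_expr))
  if (length(missing)) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  ids <- if (all_samples) annotations$sample_id else {
    group_samples(annotations, hierarchy, group)
  }
  if (length(ids) < 3L) stop("need >= 3 samples to correlate (group ", group, ")")
  e <- log_expr[, match(ids, colnames(log_expr)), drop = FALSE]
  cm <- suppressWarnings(
    stats::cor(t(e[marker_genes, , drop = FALSE]),
               t(e[gene_list, , drop = FALSE]), method = method)
  )
  # cor() yields NA for zero-variance vectors, the missing code we keep
  dimnames(cm) <- list(marker_genes, gene_list)
  structure(cm, group = group, method = method, n_samples = length(ids),
            class = c("correlation_matrix", class(cm)))
}

#' Median expression of the type-1/2/3 inflammation panels by group
#'
#' Per gene flagged type1/type2/type3 in the panel, the median log-CPM over
#' each group's samples, plus a per-gene z-score view across the group
#' columns (degenerate constant rows are flagged and set to 0).
#'
#' @param log_expr genes x samples log-expression matrix.
#' @param annotations validated sample annotations.
#' @param panel a \code{\link{gene_panel}} with inflammation-type flags.
#' @param groups column groups, default the autoantibody subgroups, IBM and
#'   NT.
#' @param hierarchy a \code{\link{myositis_hierarchy}}.
#' @return List of class \code{median_expression_matrix}: \code{median}
#'   (genes x groups), \code{z} (same shape), \code{type} (named per-gene
#'   flags), \code{degenerate} (genes with constant medians).
#' @export
inflammation_median_matrix <- function(log_expr, annotations, panel,
                                       groups = NULL,
                                       hierarchy = myositis_hierarchy()) {
  if (is.null(groups)) {
    groups <- c(hierarchy$subgroups, "IBM", hierarchy$control_group)
  }
  typed <- panel[!is.na(panel$inflammation_type), , drop = FALSE]
  typed <- typed[order(match(typed$inflammation_type,
                             c("type1", "type2", "type3"))), , drop = FALSE]
  if (!nrow(typed)) stop("panel has no type-1/2/3 flagged genes")
  genes <- intersect(typed$gene, rownames(log_expr))
  if (!length(genes)) stop("no flagged panel gene present in the matrix")
  med <- sapply(groups, function(g) {
    ids <- group_samples(annotations, hierarchy, g)
    if (!length(ids)) stop("group with zero samples: ", g)
    apply(log_expr[genes, match(ids, colnames(log_expr)), drop = FALSE],
          1L, stats::median)
  })
  med <- matrix(med, nrow = length(genes), dimnames = list(genes, groups))
  sds <- apply(med, 1L, stats::sd)
  degenerate <- rownames(med)[sds == 0]
  z <- (med - rowMeans(med)) / ifelse(sds == 0, 1, sds)
  structure(
    list(median = med, z = z,
         type = stats::setNames(typed$inflammation_type, typed$gene)[genes],
         degenerate = degenerate),
    class = "median_expression_matrix"
  )
}

#' @export
print.median_expression_matrix <- function(x, ...) {
  cat("Median log-CPM matrix:", nrow(x$median), "genes x",
      ncol(x$median), "groups\n")
  print(table(x$type))
  invisible(x)
}

#' Write a correlation matrix as TSV
#'
#' @param cm a \code{correlation_matrix}.
#' @param path output path; values at 6 significant digits.
#' @return \code{path}, invisibly.
#' @export
write_correlation_matrix <- function(cm, path) {
  df <- data.frame(marker = rownames(cm), signif(unclass(cm), 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
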