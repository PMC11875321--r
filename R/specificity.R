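#' Specificity classifier configuration
#'
#' @param alpha q-value calling threshold (default 0.001).
#' @param direction_rule require the log-fold-change sign to agree across
#'   both contrasts (default TRUE; discordant genes are dropped and logged).
#' @param nt_excluded_from_specificity NT's own sets never disqualify a
#'   myositis gene from specificity (default TRUE).
#' @return A \code{specificity_config} list.
#' @export
specificity_config <- function(alpha = 0.001, direction_rule = TRUE,
                               nt_excluded_from_specificity = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, direction_rule = direction_rule,
                 nt_excluded_from_specificity = nt_excluded_from_specificity),
            class = "specificity_config")
}

#' Call a group's over/under-expressed sets from its two contrasts
#'
#' A gene enters the overexpressed set when q < alpha in both the
#' one-vs-rest and the vs-NT contrast with positive log fold change in both;
#' underexpressed symmetrically with both negative. Genes significant in
#' both contrasts with discordant signs are excluded (and reported via
#' message). Output is ordered by ascending q versus all samples.
#'
#' @param de_vs_rest,de_vs_nt \code{de_result} objects over the same genes.
#' @param config a \code{\link{specificity_config}}.
#' @return List with ordered character vectors \code{over} and \code{under}.
#' @export
call_group_sets <- function(de_vs_rest, de_vs_nt, config = specificity_config()) {
  if (!identical(de_vs_rest$gene, de_vs_nt$gene)) {
    stop("contrast results cover different gene universes")
  }
  sig <- de_vs_rest$q < config$alpha & de_vs_nt$q < config$alpha
  concord_up <- de_vs_rest$log2FC > 0 & de_vs_nt$log2FC > 0
  concord_dn <- de_vs_rest$log2FC < 0 & de_vs_nt$log2FC < 0
  if (config$direction_rule) {
    discord <- sig & !concord_up & !concord_dn
    if (any(discord)) {
      message("discordant-sign gene(s) excluded: ",
              paste(de_vs_rest$gene[discord], collapse = ", "))
    }
  }
  ord <- order(de_vs_rest$q, de_vs_rest$p)
  over <- de_vs_rest$gene[ord][sig[ord] & concord_up[ord]]
  under <- de_vs_rest$gene[ord][sig[ord] & concord_dn[ord]]
  list(over = over, under = under)
}

#' Call NT's sets from its single one-vs-rest contrast
#'
#' @param de_vs_rest \code{de_result} for the control-vs-rest contrast.
#' @param config a \code{\link{specificity_config}}.
#' @return List with ordered vectors \code{over} and \code{under}.
#' @export
call_nt_sets <- function(de_vs_rest, config = specificity_config()) {
  sig <- de_vs_rest$q < config$alpha
  ord <- order(de_vs_rest$q, de_vs_rest$p)
  list(
    over = de_vs_rest$gene[ord][sig[ord] & de_vs_rest$log2FC[ord] > 0],
    under = de_vs_rest$gene[ord][sig[ord] & de_vs_rest$log2FC[ord] < 0]
  )
}

#' Collapse per-group sets to family level
#'
#' A family set is the union, per direction, over a clinical group and its
#' autoantibody subgroups.
#'
#' @param sets a \code{\link{group_gene_sets}} covering the analyzed groups.
#' @param hierarchy a \code{\link{myositis_hierarchy}}.
#' @return Named list per clinical group of \code{list(over=, under=)}
#'   (unordered unions).
#' @export
collapse_families <- function(sets, hierarchy) {
  out <- lapply(hierarchy$clinical_groups, function(g) {
    members <- intersect(hierarchy$families[[g]], names(sets))
    list(
      over = unique(unlist(lapply(sets[members], `[[`, "over"), use.names = FALSE)),
      under = unique(unlist(lapply(sets[members], `[[`, "under"), use.names = FALSE))
    )
  })
  names(out) <- hierarchy$clinical_groups
  out
}

#' Exclusive Venn regions of family-level sets
#'
#' For every nonempty subset S of the family labels, the exclusive region is
#' the intersection of the sets in S minus the union of the sets outside S.
#' Regions are pairwise disjoint and partition the union of all family sets.
#'
#' @param family_sets named list of character vectors (e.g. the \code{over}
#'   component of \code{\link{collapse_families}} output).
#' @return Named list of gene vectors; names join the member families with
#'   \code{"+"} in the input order. Empty regions are kept (length-0
#'   entries).
#' @export
venn_exclusive_regions <- function(family_sets) {
  labs <- names(family_sets)
  k <- length(labs)
  regions <- list()
  for (mask in 1:(2^k - 1)) {
    members <- labs[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    inside <- Reduce(intersect, family_sets[members])
    outside <- unlist(family_sets[setdiff(labs, members)], use.names = FALSE)
    regions[[paste(members, collapse = "+")]] <- setdiff(inside, outside)
  }
  regions
}

#' Look up one exclusive Venn region
#'
#' @param regions output of \code{\link{venn_exclusive_regions}}.
#' @param families character vector of family labels (any order).
#' @return Character vector of genes in exactly that region.
#' @export
venn_region <- function(regions, families) {
  hit <- vapply(strsplit(names(regions), "+", fixed = TRUE),
                function(m) setequal(m, families), logical(1))
  if (!any(hit)) stop("no such region: ", paste(families, collapse = "+"))
  regions[[which(hit)]]
}

#' Extract group-specific gene sets
#'
#' A clinical group's specific set keeps genes called by no analyzed group
#' outside its family; a subgroup's specific set keeps genes called by no
#' group other than itself and its parent clinical group (sibling subgroups
#' do disqualify). NT's sets never disqualify. Directions are handled
#' independently; within-cell order (ascending q versus all samples) is
#' preserved from the input.
#'
#' @param sets a \code{\link{group_gene_sets}} over the analyzed groups
#'   (an NT entry, if present, is ignored).
#' @param hierarchy a \code{\link{myositis_hierarchy}}.
#' @param config a \code{\link{specificity_config}}.
#' @return A \code{group_gene_sets} of specific sets, one entry per analyzed
#'   group in the input order.
#' @export
extract_specific <- function(sets, hierarchy, config = specificity_config()) {
  groups <- intersect(names(sets), hierarchy$analyzed_groups)
  competitors <- function(g) {
    allowed <- if (g %in% hierarchy$clinical_groups) {
      hierarchy$families[[g]]
    } else {
      c(g, hierarchy$parent_of[[g]])
    }
    out <- setdiff(groups, allowed)
    if (!config$nt_excluded_from_specificity) {
      out <- union(out, intersect(names(sets), hierarchy$control_group))
    }
    out
  }
  specific <- lapply(groups, function(g) {
    comp <- competitors(g)
    list(
      over = setdiff(sets[[g]]$over,
                     unlist(lapply(sets[comp], `[[`, "over"), use.names = FALSE)),
      under = setdiff(sets[[g]]$under,
                      unlist(lapply(sets[comp], `[[`, "under"), use.names = FALSE))
    )
  })
  names(specific) <- groups
  group_gene_sets(specific)
}

#' Full group-set classification from expression data
#'
#' Convenience driver: for every analyzed group, fit both contrasts on the
#' supplied log-expression and call its over/under sets; NT gets its single
#' one-vs-rest contrast. Returns the sets plus all fitted DE tables.
#'
#' @param log_expr genes x samples log-expression matrix.
#' @param annotations validated sample annotations.
#' @param hierarchy a \code{\link{myositis_hierarchy}}.
#' @param config a \code{\link{specificity_config}}.
#' @param groups analyzed groups to classify (default: all with >= 2
#'   samples).
#' @return List with \code{sets} (a \code{group_gene_sets} including NT) and
#'   \code{de} (nested list of \code{de_result}s per group).
#' @export
classify_groups <- function(log_expr, annotations,
                            hierarchy = myositis_hierarchy(),
                            config = specificity_config(),
                            groups = NULL) {
  if (is.null(groups)) {
    groups <- Filter(
      function(g) length(group_samples(annotations, hierarchy, g)) >= 2L,
      hierarchy$analyzed_groups
    )
  }
  de <- list()
  sets <- list()
  for (g in groups) {
    specs <- build_contrasts(annotations, hierarchy, g)
    de[[g]] <- lapply(specs, function(cs) fit_moderated(log_expr, cs))
    sets[[g]] <- call_group_sets(de[[g]]$vs_rest, de[[g]]$vs_nt, config)
  }
  nt <- hierarchy$control_group
  specs <- build_contrasts(annotations, hierarchy, nt)
  de[[nt]] <- lapply(specs, function(cs) fit_moderated(log_expr, cs))
  sets[[nt]] <- call_nt_sets(de[[nt]]$vs_rest, config)
  list(sets = group_gene_sets(sets), de = de)
}
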