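#' Simulation configuration
#'
#' Describes a multi-group negative-binomial count world: per-leaf-group
#' sample sizes, gene-wise log2 baselines and dispersions, log-normal
#' library sizes, planted group-specific log2 fold changes, and two latent
#' per-sample factors — immune infiltration (loading on leukocyte markers
#' and planted cytokines) and muscle regeneration (positive on regeneration
#' markers, negative on mature-muscle and mitochondrial markers) — that
#' induce the marker correlations the real biopsies show.
#'
#' Counts are drawn gene-wise NB with mean
#' \eqn{\mu_{gj} = L_j \cdot 2^{b_g + \Delta_{gj} + \lambda_g u_j + \rho_g v_j}}
#' and variance \eqn{\mu + \phi\mu^2}, where \eqn{L_j} is the sample's
#' library factor (library size / 1e6; baselines are on the log2-CPM scale).
#'
#' @param seed integer RNG seed.
#' @param group_sizes named vector of leaf-group sizes (names as in
#'   \code{\link{table1_group_sizes}}); default one quarter of the study
#'   design with a floor of 4.
#' @param n_genes total gene count (default 600: panel stand-in + markers +
#'   background).
#' @param gene_ids optional gene names; defaults to the marker genes plus
#'   numbered filler.
#' @param baseline_log2 \code{c(mean=, sd=)} of the normal draw for gene
#'   baselines (log2 CPM).
#' @param dispersion \code{c(meanlog=, sdlog=)} of the log-normal draw for
#'   gene-wise NB dispersion \eqn{\phi}.
#' @param library_size_mean expected library size (default 1e6).
#' @param library_size_log_sd sd of log library size (default 0.35).
#' @param planted_effects data.frame(gene, group, log2fc); group may be any
#'   analyzed group, background group or NT (clinical groups cover their
#'   whole family).
#' @param infiltration,regeneration lists with \code{loadings} (named
#'   numeric per gene) and \code{group_means} (named numeric per leaf or
#'   clinical group; unnamed groups get mean 0); latent values are
#'   N(mean, 1) per sample.
#' @return A validated \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1L,
                              group_sizes = NULL,
                              n_genes = 600L,
                              gene_ids = NULL,
                              baseline_log2 = c(mean = 5, sd = 2),
                              dispersion = c(meanlog = log(0.1), sdlog = 0.5),
                              library_size_mean = 1e6,
                              library_size_log_sd = 0.35,
                              planted_effects = NULL,
                              infiltration = NULL,
                              regeneration = NULL) {
  if (is.null(group_sizes)) {
    group_sizes <- pmax(4L, as.integer(round(table1_group_sizes() / 4)))
    names(group_sizes) <- names(table1_group_sizes())
  }
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% leaf_membership()$leaf)) {
    stop("group_sizes must be named by leaf groups: ",
         paste(leaf_membership()$leaf, collapse = ", "))
  }
  if (any(group_sizes < 2L)) {
    stop("all group sizes must be >= 2 (violated: ",
         paste(names(group_sizes)[group_sizes < 2L], collapse = ", "), ")")
  }
  if (is.null(gene_ids)) {
    markers <- unlist(marker_sets(), use.names = FALSE)
    if (n_genes > length(markers)) {
      gene_ids <- c(markers, sprintf("G%04d", seq_len(n_genes - length(markers))))
    } else {
      gene_ids <- sprintf("G%04d", seq_len(n_genes))
    }
  }
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids)) {
    stop("gene_ids must be ", n_genes, " unique identifiers")
  }
  if (is.null(planted_effects)) {
    planted_effects <- data.frame(gene = character(), group = character(),
                                  log2fc = numeric(), stringsAsFactors = FALSE)
  }
  h <- myositis_hierarchy()
  valid_groups <- c(h$analyzed_groups, h$background_groups, h$control_group)
  if (nrow(planted_effects)) {
    if (!all(planted_effects$gene %in% gene_ids)) {
      stop("planted effect on unknown gene(s): ",
           paste(setdiff(planted_effects$gene, gene_ids), collapse = ", "))
    }
    if (!all(planted_effects$group %in% valid_groups)) {
      stop("planted effect on unknown group(s): ",
           paste(setdiff(planted_effects$group, valid_groups), collapse = ", "))
    }
  }
  zero_factor <- list(loadings = numeric(0), group_means = numeric(0))
  infiltration <- infiltration %||% zero_factor
  regeneration <- regeneration %||% zero_factor
  for (fac in list(infiltration, regeneration)) {
    if (length(fac$loadings) && !all(names(fac$loadings) %in% gene_ids)) {
      stop("latent loading on unknown gene(s): ",
           paste(setdiff(names(fac$loadings), gene_ids), collapse = ", "))
    }
  }
  stopifnot(dispersion[["sdlog"]] >= 0, baseline_log2[["sd"]] >= 0,
            library_size_mean > 0, library_size_log_sd >= 0)
  structure(
    list(seed = as.integer(seed), group_sizes = group_sizes,
         n_genes = as.integer(n_genes), gene_ids = gene_ids,
         baseline_log2 = baseline_log2, dispersion = dispersion,
         library_size_mean = library_size_mean,
         library_size_log_sd = library_size_log_sd,
         planted_effects = planted_effects,
         infiltration = infiltration, regeneration = regeneration),
    class = "simulation_config"
  )
}

# per-sample latent mean: leaf label first, then subgroup, then clinical group
latent_means_for_samples <- function(ann, leaves, group_means) {
  if (!length(group_means)) return(rep(0, nrow(ann)))
  pick <- function(i) {
    for (key in c(leaves[i], ann$autoantibody_subgroup[i], ann$clinical_group[i])) {
      if (!is.na(key) && key %in% names(group_means)) return(group_means[[key]])
    }
    0
  }
  vapply(seq_len(nrow(ann)), pick, numeric(1))
}

#' Simulate a multi-group count matrix with ground truth
#'
#' Deterministic given (config, seed): identical configs give identical
#' output. See \code{\link{simulation_config}} for the generative model.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return List with \code{counts} (integer matrix genes x samples),
#'   \code{annotations} (sample_id, clinical_group, autoantibody_subgroup),
#'   and \code{truth}: \code{planted} (the effect table),
#'   \code{gene_params} (gene, baseline_log2, dispersion),
#'   \code{latent} (sample, infiltration, regeneration),
#'   \code{library_sizes}.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  h <- myositis_hierarchy()
  memb <- leaf_membership()

  leaves <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(leaves)
  idx <- match(leaves, memb$leaf)
  ann <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    clinical_group = memb$clinical_group[idx],
    autoantibody_subgroup = memb$autoantibody_subgroup[idx],
    stringsAsFactors = FALSE
  )

  g <- config$n_genes
  baseline <- stats::rnorm(g, config$baseline_log2[["mean"]],
                           config$baseline_log2[["sd"]])
  phi <- stats::rlnorm(g, config$dispersion[["meanlog"]],
                       config$dispersion[["sdlog"]])
  names(baseline) <- names(phi) <- config$gene_ids

  lib <- stats::rlnorm(n, log(config$library_size_mean) -
                         config$library_size_log_sd^2 / 2,
                       config$library_size_log_sd)
  u <- stats::rnorm(n) + latent_means_for_samples(
    ann, leaves, config$infiltration$group_means)
  v <- stats::rnorm(n) + latent_means_for_samples(
    ann, leaves, config$regeneration$group_means)

  lambda <- rho <- stats::setNames(numeric(g), config$gene_ids)
  lambda[names(config$infiltration$loadings)] <- config$infiltration$loadings
  rho[names(config$regeneration$loadings)] <- config$regeneration$loadings

  delta <- matrix(0, g, n, dimnames = list(config$gene_ids, ann$sample_id))
  if (nrow(config$planted_effects)) {
    for (k in seq_len(nrow(config$planted_effects))) {
      eff <- config$planted_effects[k, ]
      members <- group_samples(ann, h, eff$group)
      delta[eff$gene, match(members, ann$sample_id)] <-
        delta[eff$gene, match(members, ann$sample_id)] + eff$log2fc
    }
  }

  log2mu <- baseline + delta + outer(lambda, u) + outer(rho, v)
  mu <- sweep(2^log2mu, 2L, lib / 1e6, `*`)
  counts <- matrix(
    stats::rnbinom(g * n, mu = as.vector(mu), size = rep(1 / phi, times = n)),
    nrow = g, dimnames = list(config$gene_ids, ann$sample_id)
  )
  storage.mode(counts) <- "integer"

  list(
    counts = counts,
    annotations = ann,
    truth = list(
      planted = config$planted_effects,
      gene_params = data.frame(gene = config$gene_ids,
                               baseline_log2 = unname(baseline),
                               dispersion = unname(phi),
                               stringsAsFactors = FALSE),
      latent = data.frame(sample = ann$sample_id, infiltration = u,
                          regeneration = v, stringsAsFactors = FALSE),
      library_sizes = stats::setNames(lib, ann$sample_id)
    )
  )
}

#' Study-design simulation scenario
#'
#' A ready-made \code{\link{simulation_config}} patterned on the study's
#' group sizes (scaled by \code{scale}) with planted effects mirroring the
#' qualitative published structure: a type-1 module in IBM (CCL5, CCR5,
#' CXCR3, IFNG, CD27, IL2RG plus shared CXCL9), a distinct type-1 +
#' IFNB1-like module in DM, small modules in Jo1 and PM/Scl, and a
#' near-empty IMNM module (SPP1 only). Latent infiltration is highest in
#' IBM; regeneration is elevated in active myositis and low in NT.
#'
#' @param scale group-size multiplier in (0, 1]; every scaled size must
#'   round to >= 2.
#' @param seed RNG seed.
#' @param planted_log2fc planted effect size (default 3).
#' @return A \code{simulation_config}.
#' @export
make_table1_scenario <- function(scale = 0.25, seed = 1L, planted_log2fc = 3) {
  stopifnot(scale > 0, scale <= 1)
  sizes <- as.integer(round(scale * table1_group_sizes()))
  names(sizes) <- names(table1_group_sizes())
  if (any(sizes < 2L)) {
    stop("scale too small: group(s) ",
         paste(names(sizes)[sizes < 2L], collapse = ", "),
         " would have fewer than 2 samples")
  }
  planted <- rbind(
    data.frame(gene = c("CCL5", "CCR5", "CXCR3", "IFNG", "CD27", "IL2RG",
                        "CXCL9"),
               group = "IBM", log2fc = planted_log2fc),
    data.frame(gene = c("TNFSF10", "GDF15", "IL1RN", "IFNB1", "CXCL11"),
               group = "DM", log2fc = planted_log2fc),
    data.frame(gene = c("CXCL8", "CCL20", "CXCL9"),
               group = "Jo1", log2fc = planted_log2fc),
    data.frame(gene = c("TNFRSF25", "TNFRSF4", "CXCL13", "CXCL9"),
               group = "PM/Scl", log2fc = planted_log2fc),
    data.frame(gene = "SPP1", group = "IMNM", log2fc = planted_log2fc)
  )
  markers <- unlist(marker_sets(), use.names = FALSE)
  cytokines <- unique(planted$gene)
  n_genes <- 600L
  filler <- sprintf("G%04d", seq_len(n_genes - length(markers) - length(cytokines)))
  gene_ids <- c(markers, cytokines, filler)

  leukocytes <- unlist(marker_sets()[c("B_cell", "T_cell", "macrophage",
                                       "dendritic", "type1_markers",
                                       "type2_markers", "type3_markers")],
                       use.names = FALSE)
  infiltration <- list(
    loadings = stats::setNames(rep(0.8, length(leukocytes) + length(cytokines)),
                               c(leukocytes, cytokines)),
    group_means = c(IBM = 1.5, Jo1 = 1, "PM/Scl" = 1, DM = 0.6,
                    IMNM = 0.2, ASyS = 0.5, OTHER_INFLAMMATORY = 0.2,
                    GENETIC = 0, NT = -0.5)
  )
  regen <- marker_sets()$regeneration
  mature <- c(marker_sets()$mature_muscle, marker_sets()$mitochondrial)
  regeneration <- list(
    loadings = c(stats::setNames(rep(0.8, length(regen)), regen),
                 stats::setNames(rep(-0.8, length(mature)), mature),
                 stats::setNames(rep(0.3, length(cytokines)), cytokines)),
    group_means = c(DM = 1.2, IMNM = 1.2, ASyS = 1, IBM = 0.8, "PM/Scl" = 0.8,
                    OTHER_INFLAMMATORY = 0.5, GENETIC = 0.5, NT = -1)
  )
  simulation_config(
    seed = seed, group_sizes = sizes, n_genes = n_genes, gene_ids = gene_ids,
    planted_effects = planted, infiltration = infiltration,
    regeneration = regeneration
  )
}

#' Write a simulated data set to disk
#'
#' @param sim output of \code{\link{simulate_counts}}.
#' @param dir output directory; writes counts.tsv, annotations.tsv,
#'   truth.tsv (the planted-effect table).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(sim$truth$planted, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
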