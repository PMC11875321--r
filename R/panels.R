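#' Muscle and leukocyte marker panels
#'
#' The fixed marker panels used on the y-axis of the correlation heatmaps:
#' mature muscle, muscle regeneration, mitochondrial, B cell, T cell,
#' macrophage, dendritic cell, and type 1/2/3 inflammation markers.
#'
#' @return Named list of character vectors in display order.
#' @export
marker_sets <- function() {
  list(
    mature_muscle = c("ACTA1", "MYH1", "MYH2"),
    regeneration = c("NCAM1", "MYOG", "PAX7", "MYH3", "MYH8"),
    mitochondrial = c("MT-CO1", "MT-CO2"),
    B_cell = c("CD19", "MS4A1"),
    T_cell = c("CD3E", "CD4", "CD8A"),
    macrophage = c("CD14", "CD68"),
    dendritic = c("CD1C", "CD1E"),
    type1_markers = c("TBX21", "STAT1"),
    type2_markers = c("GATA3", "STAT6"),
    type3_markers = c("RORC", "STAT3")
  )
}

#' Packaged per-group differentially expressed gene lists
#'
#' Loads the packaged reference lists of differentially over- and
#' under-expressed genes per myositis clinical group, autoantibody subgroup
#' and NT (the published study-wide result this package's classifier is
#' validated against). Genes within each cell are in ascending order of
#' q-value versus all samples. The lone versioned Ensembl id
#' (\code{ENSG00000198223.17}) is kept verbatim as an opaque identifier.
#'
#' @return A \code{\link{group_gene_sets}} object with one entry per analyzed
#'   group plus NT.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_gene_sets.tsv",
                      package = "myoCytokines", mustWork = TRUE)
  h <- myositis_hierarchy()
  read_gene_set_table(path, groups = c(
    "DM", "Mi2", "MDA5", "NXP2", "TIF1",
    "IMNM", "HMGCR", "SRP", "ASyS", "Jo1", "IBM", "PM/Scl",
    h$control_group
  ))
}

#' Packaged per-group group-specific gene lists
#'
#' The published group-specific subsets of \code{\link{load_table2_fixture}}
#' (a gene is group-specific when no group outside the family — or, for a
#' subgroup, outside itself and its parent — also calls it). Used as the
#' exact regression target for \code{\link{extract_specific}}.
#'
#' @return A \code{\link{group_gene_sets}} object (no NT entry).
#' @export
load_table3_fixture <- function() {
  path <- system.file("extdata", "table3_specific_gene_sets.tsv",
                      package = "myoCytokines", mustWork = TRUE)
  read_gene_set_table(path, groups = c(
    "DM", "Mi2", "MDA5", "NXP2", "TIF1",
    "IMNM", "HMGCR", "SRP", "ASyS", "Jo1", "IBM", "PM/Scl"
  ))
}

# Inflammation-type flags for genes the analysis ties to a T-helper program.
# Best-effort stand-in for the full curated panel (see default_gene_panel).
inflammation_type_flags <- function() {
  c(
    CCL3 = "type1", CCL4 = "type1", CCL4L2 = "type1", CCL5 = "type1",
    CCR5 = "type1", CXCL9 = "type1", CXCL10 = "type1", CXCL11 = "type1",
    CXCR3 = "type1", IFNG = "type1", IL27 = "type1", LTA = "type1",
    IL12B = "type1", IL12RB1 = "type1", IL12RB2 = "type1", IL18 = "type1",
    IL18R1 = "type1", TNF = "type1", TNFRSF1A = "type1",
    TNFRSF25 = "type2", TNFRSF4 = "type2", AREG = "type2", CCL11 = "type2",
    CCL17 = "type2", IL13RA1 = "type2", IL5RA = "type2", TSLP = "type2",
    IL31RA = "type2", GDF15 = "type2",
    CCL20 = "type3", IL17B = "type3", IL22RA1 = "type3", IL23A = "type3",
    IL17RA = "type3"
  )
}

#' Build a gene panel
#'
#' A gene panel records, per analyzed gene, its functional category
#' (cytokine, cytokine receptor or immune checkpoint) and an optional
#' type-1/2/3 inflammation flag, and carries the marker panels as an
#' attribute. The default panel is a documented stand-in: the union of the
#' packaged reference gene lists plus the marker genes, with heuristic
#' category labels. Users with the full curated 338-gene panel supply it via
#' \code{\link{read_gene_panel}}.
#'
#' @param genes character vector of gene ids; NULL for the default panel.
#' @param category per-gene category; guessed heuristically when NULL.
#' @param inflammation_type optional per-gene flag in type1/type2/type3 (NA
#'   for none).
#' @return data.frame (gene, category, inflammation_type) of class
#'   \code{gene_panel} with attribute \code{marker_sets}.
#' @export
gene_panel <- function(genes, category = NULL, inflammation_type = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop("duplicate genes in panel: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (is.null(category)) category <- guess_gene_category(genes)
  if (is.null(inflammation_type)) {
    flags <- inflammation_type_flags()
    inflammation_type <- unname(flags[genes])
  }
  stopifnot(length(category) == length(genes),
            length(inflammation_type) == length(genes))
  bad <- setdiff(unique(stats::na.omit(inflammation_type)),
                 c("type1", "type2", "type3"))
  if (length(bad)) stop("invalid inflammation_type: ", paste(bad, collapse = ", "))
  structure(
    data.frame(gene = genes, category = category,
               inflammation_type = inflammation_type, stringsAsFactors = FALSE),
    marker_sets = marker_sets(),
    class = c("gene_panel", "data.frame")
  )
}

guess_gene_category <- function(genes) {
  checkpoints <- c("CD274", "CTLA4", "PDCD1", "PDCD1LG2", "CD28", "CD80",
                   "CD86", "CD27", "CD40", "CD40LG", "CD70", "ICOS",
                   "TNFRSF9", "TNFRSF4", "TNFRSF18", "LAG3", "HAVCR2",
                   "TIGIT", "SIGIRR")
  receptor_pat <- "(^CCR|^CXCR|^XCR|^ACKR|R[0-9AB]*$|RA$|RB$|RG$|RAP$|^TNFRSF|^IFNAR|^IFNGR|^IL[0-9]+R|^LTBR$|^FAS$|^OSMR$|^CSF[0-9]R|^FLT3$|^ITGA|^NGFR$|^TGFBR)"
  ifelse(genes %in% checkpoints, "immune_checkpoint",
         ifelse(grepl(receptor_pat, genes), "cytokine_receptor", "cytokine"))
}

#' Default packaged gene panel
#'
#' @return A \code{\link{gene_panel}} covering the packaged reference gene
#'   lists and marker genes.
#' @export
default_gene_panel <- function() {
  t2 <- load_table2_fixture()
  genes <- unique(c(
    unlist(lapply(t2, function(s) c(s$over, s$under)), use.names = FALSE),
    unlist(marker_sets(), use.names = FALSE)
  ))
  gene_panel(sort(genes))
}

#' Read a gene panel config
#'
#' TSV with columns \code{gene}, \code{category}, \code{inflammation_type}
#' (may be empty). Marker panels are fixed (\code{\link{marker_sets}}).
#'
#' @param path TSV path.
#' @return A \code{\link{gene_panel}}.
#' @export
read_gene_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  gene_panel(df$gene, df$category, df$inflammation_type)
}

#' Check a panel against a count matrix
#'
#' Panel genes absent from the counts are reported (message + return value),
#' never silently dropped.
#'
#' @param panel a \code{gene_panel}.
#' @param counts count or expression matrix with gene rownames.
#' @return Character vector of missing genes (possibly empty), invisibly
#'   when none.
#' @export
check_panel_coverage <- function(panel, counts) {
  missing <- setdiff(panel$gene, rownames(counts))
  if (length(missing)) {
    message("panel genes missing from matrix (", length(missing), "): ",
            paste(missing, collapse = ", "))
    return(missing)
  }
  invisible(character())
}
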