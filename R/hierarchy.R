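#' Myositis group hierarchy
#'
#' Defines the clinical groups, autoantibody subgroups and their nesting used
#' throughout the package. Clinical groups are dermatomyositis (DM),
#' immune-mediated necrotizing myopathy (IMNM), anti-synthetase syndrome
#' (ASyS), inclusion body myositis (IBM) and anti-PM/Scl overlap myositis
#' (PM/Scl). Subgroups are serology-defined: Mi2/MDA5/NXP2/TIF1 under DM,
#' HMGCR/SRP under IMNM, Jo1 under ASyS; PM/Scl is simultaneously a clinical
#' group and its own (only) subgroup. Two background groups (other
#' inflammatory and genetic myopathies) contribute samples to "all samples"
#' contrasts but are never analyzed themselves; NT (normal tissue) is the
#' control group.
#'
#' @return An object of class \code{group_hierarchy}: a list with elements
#'   \code{analyzed_groups}, \code{clinical_groups}, \code{subgroups},
#'   \code{parent_of} (named character, subgroup -> clinical group),
#'   \code{families} (named list, clinical group -> itself plus subgroups),
#'   \code{background_groups} and \code{control_group}.
#' @examples
#' h <- myositis_hierarchy()
#' h$families$DM
#' @export
myositis_hierarchy <- function() {
  clinical <- c("DM", "IMNM", "ASyS", "IBM", "PM/Scl")
  parent_of <- c(
    Mi2 = "DM", MDA5 = "DM", NXP2 = "DM", TIF1 = "DM",
    HMGCR = "IMNM", SRP = "IMNM", Jo1 = "ASyS", "PM/Scl" = "PM/Scl"
  )
  subgroups <- names(parent_of)
  families <- lapply(clinical, function(g) {
    unique(c(g, subgroups[parent_of == g]))
  })
  names(families) <- clinical
  structure(
    list(
      analyzed_groups = unique(c(clinical, subgroups)),
      clinical_groups = clinical,
      subgroups = subgroups,
      parent_of = parent_of,
      families = families,
      background_groups = c("OTHER_INFLAMMATORY", "GENETIC"),
      control_group = "NT"
    ),
    class = "group_hierarchy"
  )
}

#' @export
print.group_hierarchy <- function(x, ...) {
  cat("Myositis group hierarchy\n")
  for (g in x$clinical_groups) {
    cat(sprintf("  %-7s family: %s\n", g, paste(x$families[[g]], collapse = ", ")))
  }
  cat("  background:", paste(x$background_groups, collapse = ", "), "\n")
  cat("  control:", x$control_group, "\n")
  invisible(x)
}

#' Family of a group
#'
#' The family of a clinical group is the group together with its autoantibody
#' subgroups; the family of a subgroup is the family of its parent. Families
#' are the unit at which Venn exclusivity and specificity are evaluated.
#'
#' @param hierarchy a \code{\link{myositis_hierarchy}} object.
#' @param group a clinical group or subgroup label.
#' @return Character vector of group labels.
#' @export
group_family <- function(hierarchy, group) {
  stopifnot(inherits(hierarchy, "group_hierarchy"))
  if (group %in% hierarchy$clinical_groups) {
    return(hierarchy$families[[group]])
  }
  if (group %in% hierarchy$subgroups) {
    return(hierarchy$families[[hierarchy$parent_of[[group]]]])
  }
  stop("unknown analyzed group: ", group)
}

#' Samples belonging to a group
#'
#' Clinical-group membership includes the group's subgroups' samples (they
#' share the clinical_group label); subgroup membership is by autoantibody
#' label; NT and background groups are matched on clinical_group.
#'
#' @param annotations data.frame with columns \code{sample_id},
#'   \code{clinical_group}, \code{autoantibody_subgroup}.
#' @param hierarchy a \code{group_hierarchy}.
#' @param group group label.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(annotations, hierarchy, group) {
  stopifnot(inherits(hierarchy, "group_hierarchy"))
  known <- c(
    hierarchy$analyzed_groups, hierarchy$background_groups,
    hierarchy$control_group
  )
  if (!group %in% known) stop("unknown group: ", group)
  if (group %in% hierarchy$subgroups && group != "PM/Scl") {
    keep <- !is.na(annotations$autoantibody_subgroup) &
      annotations$autoantibody_subgroup == group
  } else {
    keep <- annotations$clinical_group == group
  }
  annotations$sample_id[keep]
}

#' Validate sample annotations against the hierarchy
#'
#' Checks that every clinical group label is known and that each subgroup
#' label, when present, is consistent with the subgroup-to-parent mapping
#' ("other" is allowed under any clinical group and marks samples that carry
#' no analyzed autoantibody).
#'
#' @inheritParams group_samples
#' @return The annotations, invisibly, with subgroup \code{""} mapped to
#'   \code{NA}.
#' @export
validate_annotations <- function(annotations, hierarchy = myositis_hierarchy()) {
  req <- c("sample_id", "clinical_group", "autoantibody_subgroup")
  if (!all(req %in% names(annotations))) {
    stop("annotations must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(annotations$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(annotations$sample_id[duplicated(annotations$sample_id)]),
               collapse = ", "))
  }
  known <- c(hierarchy$clinical_groups, hierarchy$background_groups,
             hierarchy$control_group)
  bad <- setdiff(unique(annotations$clinical_group), known)
  if (length(bad)) stop("unknown clinical group label(s): ", paste(bad, collapse = ", "))
  sub <- annotations$autoantibody_subgroup
  sub[!is.na(sub) & sub == ""] <- NA
  has <- !is.na(sub) & sub != "other"
  if (any(has)) {
    unknown <- setdiff(unique(sub[has]), hierarchy$subgroups)
    if (length(unknown)) {
      stop("unknown autoantibody subgroup(s): ", paste(unknown, collapse = ", "))
    }
    expected <- hierarchy$parent_of[sub[has]]
    mism <- expected != annotations$clinical_group[has]
    if (any(mism)) {
      offending <- annotations$sample_id[has][mism]
      stop("subgroup inconsistent with clinical group for sample(s): ",
           paste(offending, collapse = ", "))
    }
  }
  annotations$autoantibody_subgroup <- sub
  invisible(annotations)
}

#' Study design group sizes
#'
#' Sample counts per leaf group in the study design this package models:
#' DM (105 = Mi2 22 + MDA5 11 + NXP2 21 + TIF1 28 + other 23), IMNM
#' (80 = HMGCR 60 + SRP 20), ASyS (65 = Jo1 37 + other 28), IBM 53,
#' PM/Scl 19, other inflammatory myopathies 239, genetic myopathies 71 and
#' 37 normal-tissue controls; 669 biopsies in total.
#'
#' @return Named integer vector of leaf-group sizes. Names \code{DM_other}
#'   and \code{ASyS_other} denote clinical-group members without an analyzed
#'   autoantibody subgroup.
#' @export
table1_group_sizes <- function() {
  c(
    Mi2 = 22L, MDA5 = 11L, NXP2 = 21L, TIF1 = 28L, DM_other = 23L,
    HMGCR = 60L, SRP = 20L, Jo1 = 37L, ASyS_other = 28L,
    IBM = 53L, "PM/Scl" = 19L,
    OTHER_INFLAMMATORY = 239L, GENETIC = 71L, NT = 37L
  )
}

# leaf label -> (clinical_group, subgroup) used by the simulator and the
# annotation summariser; subgroup NA means none.
leaf_membership <- function() {
  data.frame(
    leaf = names(table1_group_sizes()),
    clinical_group = c(
      "DM", "DM", "DM", "DM", "DM",
      "IMNM", "IMNM", "ASyS", "ASyS",
      "IBM", "PM/Scl", "OTHER_INFLAMMATORY", "GENETIC", "NT"
    ),
    autoantibody_subgroup = c(
      "Mi2", "MDA5", "NXP2", "TIF1", "other",
      "HMGCR", "SRP", "Jo1", "other",
      NA, "PM/Scl", NA, NA, NA
    ),
    stringsAsFactors = FALSE
  )
}
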