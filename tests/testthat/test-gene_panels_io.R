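test_that("count matrix TSV round-trips exactly", {
  m <- matrix(c(1L, 3L, 2L, 4L), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(m, path)
  expect_identical(read_counts(path), m)

  sim <- simulate_counts(simulation_config(
    seed = 3, group_sizes = c(IBM = 30L, NT = 30L), n_genes = 500L))
  write_counts(sim$counts, path)
  expect_identical(read_counts(path), sim$counts)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_counts(sim$counts, mtx)
  expect_identical(read_counts(mtx), sim$counts)
})

test_that("count validation rejects malformed input", {
  m <- matrix(c(1L, -3L, 2L, 4L), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = rownames(m), m)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_counts(path), "negative count for gene gB, sample s1")

  expect_error(validate_counts(matrix(1:4, 2)), "rownames")
  dup <- matrix(1:4, 2, dimnames = list(c("g", "g"), c("a", "b")))
  expect_error(validate_counts(dup), "duplicate gene")
  z <- matrix(c(1L, 1L, 0L, 0L), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(validate_counts(z), "zero total count: b")
  writeLines("justonecolumn", path)
  expect_error(read_counts(path), "malformed header")
})

test_that("annotation reading validates against the hierarchy", {
  h <- myositis_hierarchy()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tclinical_group\tautoantibody_subgroup",
               "s1\tIBM\t", "s2\tDM\tMi2"), path)
  ann <- read_annotations(path, h, quiet = TRUE)
  expect_true(is.na(ann$autoantibody_subgroup[1]))
  expect_identical(ann$autoantibody_subgroup[2], "Mi2")

  writeLines(c("sample_id\tclinical_group\tautoantibody_subgroup",
               "s2\tDM\tJo1"), path)
  expect_error(read_annotations(path, h, quiet = TRUE),
               "subgroup inconsistent with clinical group for sample\\(s\\): s2")
  writeLines(c("sample_id\tclinical_group\tautoantibody_subgroup",
               "s2\tDMX\t"), path)
  expect_error(read_annotations(path, h, quiet = TRUE), "unknown clinical group")
})

test_that("study-design annotation file reproduces the published group sizes", {
  ann <- table1_annotations()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  back <- read_annotations(path, quiet = TRUE)
  expect_equal(nrow(back), 669L)
  sizes <- table(back$clinical_group)
  expect_equal(sizes[["DM"]], 105L)
  expect_equal(sizes[["IMNM"]], 80L)
  expect_equal(sizes[["ASyS"]], 65L)
  expect_equal(sizes[["IBM"]], 53L)
  expect_equal(sizes[["PM/Scl"]], 19L)
  expect_equal(sizes[["OTHER_INFLAMMATORY"]], 239L)
  expect_equal(sizes[["GENETIC"]], 71L)
  expect_equal(sizes[["NT"]], 37L)
  expect_identical(back$autoantibody_subgroup, ann$autoantibody_subgroup)
})

test_that("hierarchy families partition the analyzed groups", {
  h <- myositis_hierarchy()
  expect_setequal(h$families$DM, c("DM", "Mi2", "MDA5", "NXP2", "TIF1"))
  expect_setequal(h$families$IMNM, c("IMNM", "HMGCR", "SRP"))
  expect_setequal(h$families$ASyS, c("ASyS", "Jo1"))
  expect_identical(h$families$IBM, "IBM")
  expect_identical(h$families$`PM/Scl`, "PM/Scl")
  expect_setequal(unlist(h$families), h$analyzed_groups)
  expect_identical(group_family(h, "Jo1"), h$families$ASyS)
  expect_false(any(c(h$background_groups, h$control_group) %in% h$analyzed_groups))
})

test_that("packaged reference gene lists match the published counts", {
  t2 <- load_table2_fixture()
  expect_identical(t2$IBM$over[1], "CCL5")
  expect_length(t2$IMNM$over, 9)
  expect_identical(t2$MDA5$over, "TNFSF10")
  expect_length(t2$NT$under, 117)
  expect_true("MSTN" %in% t2$NT$over)
  expect_true("ENSG00000198223.17" %in% t2$NT$under)
  # specific lists are subset views of the called lists, cell by cell
  t3 <- load_table3_fixture()
  for (g in names(t3)) {
    expect_true(all(t3[[g]]$over %in% t2[[g]]$over), label = paste(g, "over"))
    expect_true(all(t3[[g]]$under %in% t2[[g]]$under), label = paste(g, "under"))
  }
})

test_that("gene-set tables round-trip and count correctly", {
  empty <- group_gene_sets(list(DM = list(over = character(), under = character())))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_set_table(empty, path)
  expect_identical(readLines(path), "group\tdirection\trank\tgene")

  t2 <- load_table2_fixture()
  write_gene_set_table(t2, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(sum(df$group == "IBM" & df$direction == "over"), 71L)
  back <- read_gene_set_table(path, groups = names(t2))
  expect_equal(back, t2)
})

test_that("gene panels validate and report missing genes", {
  p <- default_gene_panel()
  expect_false(anyDuplicated(p$gene) > 0)
  expect_true(all(p$category %in%
                    c("cytokine", "cytokine_receptor", "immune_checkpoint")))
  expect_error(gene_panel(c("A", "A")), "duplicate genes")

  counts <- toy_counts()
  small <- gene_panel(c("g1", "g2", "NOTTHERE"))
  expect_message(miss <- check_panel_coverage(small, counts), "NOTTHERE")
  expect_identical(miss, "NOTTHERE")
  expect_silent(check_panel_coverage(gene_panel(c("g1", "g2")), counts))

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcategory\tinflammation_type",
               "IFNG\tcytokine\ttype1", "CCR5\tcytokine_receptor\t"), path)
  rp <- read_gene_panel(path)
  expect_identical(rp$inflammation_type, c("type1", NA))
})
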