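feat <- function(id, kind, start, end, strand = "+", chrom = "chrX") {
  tibble::tibble(feature_id = id, kind = kind, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand)
}

test_that("containment is full-interval and boundary-inclusive", {
  gene <- feat("G1", "gene", 1000, 2000)
  expect_equal(nrow(map_hosted_mirs(gene, feat("m1", "mirna", 2500, 2580))), 0L)
  # interval equal to the gene interval is hosted
  expect_equal(map_hosted_mirs(gene, feat("m2", "mirna", 1000, 2000))$mir, "m2")
  # straddling the boundary is not containment
  expect_equal(nrow(map_hosted_mirs(gene, feat("m3", "mirna", 1990, 2010))), 0L)
  # nested genes both containing one miR yield two pairs
  genes <- dplyr::bind_rows(feat("OUTER", "gene", 100, 5000),
                            feat("INNER", "gene", 1000, 2000))
  pairs <- map_hosted_mirs(genes, feat("m4", "mirna", 1500, 1580))
  expect_setequal(pairs$gene, c("OUTER", "INNER"))
})

test_that("strand policy restricts matches and is monotone", {
  gene <- feat("G1", "gene", 1000, 2000, strand = "+")
  anti <- feat("m1", "mirna", 1100, 1180, strand = "-")
  expect_equal(nrow(map_hosted_mirs(gene, anti, "same")), 0L)
  expect_equal(nrow(map_hosted_mirs(gene, anti, "ignore")), 1L)

  withr::with_seed(7, {
    for (i in 1:10) {
      fx <- random_features(20, 40)
      same <- map_hosted_mirs(fx$genes, fx$mirs, "same")
      ignore <- map_hosted_mirs(fx$genes, fx$mirs, "ignore")
      expect_gte(nrow(ignore), nrow(same))
      expect_true(all(paste(same$gene, same$mir) %in%
                        paste(ignore$gene, ignore$mir)))
    }
  })
})

test_that("containment mapping equals the brute-force oracle on random annotations", {
  withr::with_seed(4242, {
    for (i in 1:25) {
      fx <- random_features(sample(5:60, 1), sample(5:120, 1))
      got <- map_hosted_mirs(fx$genes, fx$mirs, strand_policy = "ignore")
      expect_identical(sort(paste(got$gene, got$mir)),
                       oracle_containment(fx$genes, fx$mirs))
    }
  })
})

test_that("the reference annotation yields the 12 known hosting pairs over 6 genes", {
  d <- fixture_dir()
  genes <- read_gff3(file.path(d, "genes.gff3"), "gene")
  mirs <- read_gff3(file.path(d, "mirs.gff3"), "mirna")
  escapers <- genes[genes$feature_id %in% names(HOST_MIR_MAP), ]
  pairs <- map_hosted_mirs(escapers, mirs)
  expect_equal(nrow(pairs), 12L)
  expect_equal(length(unique(pairs$gene)), 6L)
  expect_true(nrow(mirs) >= 50 + 12)  # decoy miRs were present and excluded
  got <- split(pairs$mir, pairs$gene)
  for (g in names(HOST_MIR_MAP)) expect_setequal(got[[g]], HOST_MIR_MAP[[g]])
  # row-for-row: CTPS2 hosts the miR-548am precursor, HTR2C six miRs
  expect_equal(got$CTPS2, "hsa-miR-548am")
  expect_equal(length(got$HTR2C), 6L)
})

test_that("tissue escape filter partitions input with one reason per exclusion", {
  tab <- tibble::tibble(
    gene = c("CSF2RA", "HTR2C", "VGLL1", "GABRE", "CTPS2", "PUDP"),
    tissue = "fibroblast",
    expressed = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    logfc = c(NA, NA, NA, -0.45, 0.35, 0.52)
  )
  genes <- c(tab$gene, "NOVELGENE")
  res <- filter_tissue_escape(genes, tab, "fibroblast")
  expect_setequal(res$retained, c("CTPS2", "PUDP"))
  reasons <- setNames(res$exclusions$reason, res$exclusions$gene)
  expect_equal(unname(reasons[c("CSF2RA", "HTR2C", "VGLL1")]),
               rep("not_expressed", 3))
  expect_equal(unname(reasons["GABRE"]), "nonpositive_logfc")
  expect_equal(unname(reasons["NOVELGENE"]), "not_in_table")
  # partition: retained and excluded are disjoint and cover the input
  expect_setequal(c(res$retained, res$exclusions$gene), genes)
  expect_length(intersect(res$retained, res$exclusions$gene), 0)
  # zero logFC excludes (strictly positive required)
  res0 <- filter_tissue_escape("X1", tibble::tibble(
    gene = "X1", tissue = "fibroblast", expressed = TRUE, logfc = 0), "fibroblast")
  expect_equal(res0$exclusions$reason, "nonpositive_logfc")
  expect_error(filter_tissue_escape("CTPS2", tab, "liver"), "absent")
})

test_that("negative-control selection prefers family members in XCI-subject loci", {
  inact <- dplyr::bind_rows(feat("XI1", "gene", 1000, 2000),
                            feat("XI2", "gene", 5000, 6000))
  mirs <- dplyr::bind_rows(
    feat("hsa-miR-548ax", "mirna", 1100, 1180),
    feat("hsa-miR-23c", "mirna", 5100, 5180),
    feat("hsa-miR-999", "mirna", 9000, 9080)  # not in any locus
  )
  sel <- select_control_mirs(mirs, hosted_mir_ids = "hsa-miR-548am",
                             inactivated_genes = inact, k = 2,
                             candidate_mirs = "hsa-miR-548am-5p")
  expect_equal(sel, c("hsa-miR-548ax", "hsa-miR-23c"))
  expect_equal(select_control_mirs(mirs, character(), inact, k = 0), character())
  # vacuous pool: everything already hosted in escapers
  expect_warning(
    sel0 <- select_control_mirs(mirs, c("hsa-miR-548ax", "hsa-miR-23c"), inact, k = 2),
    "no eligible")
  expect_equal(sel0, character())
})
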