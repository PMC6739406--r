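test_that("escape-table generation plants the requested set algebra", {
  d <- withr::local_tempdir()
  out <- gen_escape_tables(d, n_escape_a = 10, n_escape_b = 12, n_overlap = 4,
                           n_inactivated = 5, n_variable = 3,
                           extras_a = c(dup = 2, withdrawn = 2, unmatched = 2),
                           extras_b = c(dup = 1, withdrawn = 1, unmatched = 1),
                           anchor_genes = FALSE, seed = 3)
  map <- read_symbol_map(out$paths$symbol_map)
  carrel <- classify_carrel(read_escape_table(out$paths$carrel, "carrel"))
  cotton <- classify_cotton(read_escape_table(out$paths$cotton, "cotton"))
  a <- normalize_symbols(carrel$gene_id[carrel$category == "escape"], map)$symbols
  b <- normalize_symbols(cotton$gene_id[cotton$category == "escape"], map)$symbols
  r <- reconcile(a, b)
  expect_equal(r$sizes$set_a, 10L)
  expect_equal(r$sizes$set_b, 12L)
  expect_equal(r$sizes$intersection, 4L)
  expect_equal(r$sizes$union, 18L)
  # raw lists exceed valid counts (normalization is exercised)
  expect_gt(sum(carrel$category == "escape"), 10L)
  expect_error(gen_escape_tables(d, n_escape_a = 3, n_escape_b = 3, n_overlap = 5,
                                 anchor_genes = FALSE), "n_overlap")
})

test_that("generated tables pass back through the pipeline across random specs", {
  withr::with_seed(99, {
    for (i in 1:10) {
      na <- sample(5:40, 1); nb <- sample(5:40, 1)
      nov <- sample(0:min(na, nb), 1)
      d <- withr::local_tempdir()
      out <- gen_escape_tables(d, na, nb, nov, n_inactivated = 4, n_variable = 2,
                               extras_a = c(dup = 2, withdrawn = 1, unmatched = 3),
                               extras_b = c(dup = 0, withdrawn = 2, unmatched = 1),
                               anchor_genes = FALSE, seed = i)
      map <- read_symbol_map(out$paths$symbol_map)
      carrel <- classify_carrel(read_escape_table(out$paths$carrel, "carrel"))
      cotton <- classify_cotton(read_escape_table(out$paths$cotton, "cotton"))
      a <- normalize_symbols(carrel$gene_id[carrel$category == "escape"], map)$symbols
      b <- normalize_symbols(cotton$gene_id[cotton$category == "escape"], map)$symbols
      r <- reconcile(a, b)
      expect_equal(r$sizes$set_a, na)
      expect_equal(r$sizes$set_b, nb)
      expect_equal(r$sizes$intersection, nov)
      expect_equal(r$sizes$union, na + nb - nov)
    }
  })
})

test_that("generators are deterministic for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_escape_tables(d1, seed = 7); gen_escape_tables(d2, seed = 7)
  for (f in c("carrel_calls.tsv", "cotton_calls.tsv", "symbol_map.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  gen_annotation(d1, seed = 7); gen_annotation(d2, seed = 7)
  expect_identical(readLines(file.path(d1, "mirs.gff3")),
                   readLines(file.path(d2, "mirs.gff3")))
  q1 <- gen_qpcr(seed = 5); q2 <- gen_qpcr(seed = 5)
  expect_identical(q1, q2)
})

test_that("annotation generation honors arbitrary hosting specs and rejects bad ones", {
  d <- withr::local_tempdir()
  hosting <- list(GA = c("hsa-miR-1", "hsa-miR-2"), GB = "hsa-miR-3",
                  GC = character())
  out <- gen_annotation(d, hosting = hosting, other_genes = c("GX", "GY"),
                        n_decoys = 20, seed = 2)
  genes <- read_gff3(out$paths$genes, "gene")
  mirs <- read_gff3(out$paths$mirs, "mirna")
  pairs <- map_hosted_mirs(genes, mirs)
  expect_equal(nrow(pairs), 3L)
  expect_setequal(pairs$mir[pairs$gene == "GA"], c("hsa-miR-1", "hsa-miR-2"))
  # decoys-only spec yields zero pairs
  out0 <- gen_annotation(withr::local_tempdir(), hosting = list(),
                         other_genes = c("GX"), n_decoys = 15, seed = 2)
  expect_equal(nrow(map_hosted_mirs(read_gff3(out0$paths$genes, "gene"),
                                    read_gff3(out0$paths$mirs, "mirna"))), 0L)
  expect_error(gen_annotation(d, hosting = list(GA = "m", GA = "m2")), "duplicated")
})

test_that("the fixture bundle is byte-stable and self-consistent with its manifest", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- fixture_bundle(d1); fixture_bundle(d2)
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  rep <- run_all(file.path(d1, "config.yaml"))
  exp <- b1$manifest$expected
  expect_equal(rep$escape$sizes$union, exp$n_union)
  expect_equal(rep$hosting$n_host_genes, exp$n_host_genes)
  expect_equal(rep$hosting$n_pairs, exp$n_hosting_pairs)
  expect_setequal(rep$tissue$retained, exp$tissue_retained)
  expect_setequal(rep$controls, exp$control_mirs)
  expect_equal(rep$ranking$mir_id[1], exp$top_candidate)
})
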