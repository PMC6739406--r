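test_that("target extraction is exact-ID and arm-specific", {
  ints <- tibble::tibble(
    mir_id = c("hsa-miR-548am-5p", "hsa-miR-548am-5p", "hsa-miR-548am-3p"),
    gene = c("BAX", "XIAP", "OTHER"),
    evidence = "synthetic"
  )
  expect_equal(get_targets("hsa-miR-548am-5p", ints), c("BAX", "XIAP"))
  expect_equal(get_targets("hsa-miR-548am-3p", ints), "OTHER")
  expect_equal(get_targets("hsa-miR-nope", ints), character())
})

test_that("the reference target table gives 332 and 3 validated targets", {
  ints <- read_targets(file.path(fixture_dir(), "targets.tsv"))
  t5p <- get_targets("hsa-miR-548am-5p", ints)
  expect_length(t5p, 332L)
  expect_true(all(APOPTOSIS_GENES %in% t5p))
  expect_length(get_targets("hsa-miR-4767", ints), 3L)
})

test_that("hypergeometric p matches the counting oracle, frozen case included", {
  # C(20,5) draws, 1126 of them share >= 3 of a 5-gene set
  fx <- gen_planted_enrichment(20, 5, 5, 3)
  res <- hypergeom_enrich(fx$query, fx$sets, fx$background)
  expect_equal(res$p_value, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$k, 3L)

  # exhaustive over all feasible (N, K, n, k) with N <= 25
  for (N in 1:25) {
    for (K in 0:N) {
      for (n in 0:N) {
        k <- max(0, n + K - N):min(K, n)
        p_impl <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        p_oracle <- vapply(k, function(kk) oracle_hypergeom_p(N, K, n, kk),
                           numeric(1))
        expect_equal(p_impl, p_oracle, tolerance = 1e-12)
      }
    }
  }
})

test_that("degenerate enrichment cases behave as specified", {
  # k = 0, K = 0: impossible to overlap, p = 1
  fx <- gen_planted_enrichment(10, 0, 4, 0)
  expect_equal(hypergeom_enrich(fx$query, fx$sets, fx$background)$p_value, 1)
  # query is the whole background: k = K forced, p = 1
  fx <- gen_planted_enrichment(10, 4, 10, 4)
  res <- hypergeom_enrich(fx$query, fx$sets, fx$background)
  expect_equal(res$k, res$K)
  expect_equal(res$p_value, 1)
  expect_error(hypergeom_enrich("X", list(S = "A"), character()), "empty")
  expect_error(hypergeom_enrich(c("A", "ZZZ"), list(S = "A"), c("A", "B")), "ZZZ")
})

test_that("planted enrichment configurations reproduce their analytic p exactly", {
  cases <- list(c(100, 20, 10, 6), c(400, 40, 20, 8), c(50, 25, 12, 10))
  for (cs in cases) {
    fx <- gen_planted_enrichment(cs[1], cs[2], cs[3], cs[4])
    res <- hypergeom_enrich(fx$query, fx$sets, fx$background)
    expect_equal(res$k, cs[4])
    expect_equal(res$p_value,
                 oracle_hypergeom_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
})

test_that("null simulation holds the nominal type-I error", {
  # N = 40, K = 10, n = 10: the largest attainable tail probability at or
  # below 0.05 is 0.0498, so the discrete test is essentially exact here
  N <- 40L; K <- 10L; n <- 10L
  background <- sprintf("G%03d", seq_len(N))
  sets <- list(S = background[seq_len(K)])
  hits <- withr::with_seed(2024, vapply(seq_len(2000), function(i) {
    q <- sample(background, n)
    hypergeom_enrich(q, sets, background)$p_value <= 0.05
  }, logical(1)))
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("BH adjustment matches hand computation and is permutation-invariant", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 3)), rep(0.2, 3))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(1.5), "0, 1")

  withr::with_seed(5, {
    p <- runif(20, 1e-4, 1)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))                      # adjusted >= raw
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p)) # monotone in rank
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])      # permutation-invariant
  })
})

test_that("prioritization orders candidates by the documented key", {
  cands <- tibble::tibble(
    mir_id = c("hsa-miR-4767", "hsa-miR-548am-5p", "hsa-miR-548am-3p"),
    host_gene = c("PUDP", "CTPS2", "CTPS2"),
    tissue_supported = TRUE,
    n_targets = c(3L, 332L, 20L)
  )
  enr <- tibble::tibble(
    mir_id = "hsa-miR-548am-5p", set_name = "APOPTOSIS", p_adjusted = 0.013
  )
  r <- prioritize(cands, enr, "APOPTOSIS")
  expect_equal(r$mir_id[r$rank == 1], "hsa-miR-548am-5p")
  expect_equal(r$mir_id, c("hsa-miR-548am-5p", "hsa-miR-548am-3p", "hsa-miR-4767"))
  expect_equal(r$rank, 1:3)
  expect_true(r$pathway_enriched[1])
  expect_false(any(r$pathway_enriched[-1]))

  # single candidate gets rank 1
  r1 <- prioritize(cands[1, ], enr, "APOPTOSIS")
  expect_equal(r1$rank, 1L)

  # identical on all keys except ID: lexicographic tie-break
  twins <- tibble::tibble(mir_id = c("hsa-miR-b", "hsa-miR-a"),
                          host_gene = "G", tissue_supported = TRUE,
                          n_targets = 50L)
  rt <- prioritize(twins, enr[0, ], "APOPTOSIS")
  expect_equal(rt$mir_id, c("hsa-miR-a", "hsa-miR-b"))

  # empty candidate list yields an empty ranking
  expect_equal(nrow(prioritize(cands[0, ], enr, "APOPTOSIS")), 0L)
})
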