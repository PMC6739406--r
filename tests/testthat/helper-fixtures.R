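# Shared oracles and fixtures. Oracles are written independently of the
# implementation paths they check (counting identities and double loops,
# not phyper/findOverlaps).

# Upper-tail hypergeometric probability by direct counting:
# P(X >= k) = sum_j C(K, j) C(N-K, n-j) / C(N, n) over feasible j >= k.
oracle_hypergeom_p <- function(N, K, n, k) {
  js <- max(k, 0):min(K, n)
  js <- js[js >= (n - (N - K))]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# All-pairs interval containment by explicit double loop.
oracle_containment <- function(genes, mirs) {
  out <- character(0)
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(mirs))) {
      if (genes$chrom[i] == mirs$chrom[j] &&
          genes$start[i] <= mirs$start[j] &&
          mirs$end[j] <= genes$end[i]) {
        out <- c(out, paste(genes$feature_id[i], mirs$feature_id[j]))
      }
    }
  }
  sort(out)
}

# Random feature tables for property tests.
random_features <- function(n_genes, n_mirs, chroms = c("chrX", "chr7")) {
  mk <- function(n, prefix, kind, min_w, max_w) {
    start <- sample.int(500000L, n, replace = TRUE)
    width <- sample(min_w:max_w, n, replace = TRUE)
    tibble::tibble(
      feature_id = sprintf("%s%03d", prefix, seq_len(n)),
      kind = kind,
      chrom = sample(chroms, n, replace = TRUE),
      start = start,
      end = start + width - 1L,
      strand = sample(c("+", "-", "unknown"), n, replace = TRUE,
                      prob = c(0.45, 0.45, 0.1))
    )
  }
  list(genes = mk(n_genes, "G", "gene", 5000L, 60000L),
       mirs = mk(n_mirs, "hsa-miR-t", "mirna", 60L, 120L))
}

# One reference fixture bundle per test run, built lazily and reused.
fixture_env <- new.env(parent = emptyenv())
fixture_dir <- function() {
  if (is.null(fixture_env$dir)) {
    d <- file.path(tempdir(), "xcimir-fixture")
    fixture_bundle(d)
    fixture_env$dir <- d
  }
  fixture_env$dir
}

fixture_report <- function() {
  if (is.null(fixture_env$report)) {
    fixture_env$report <- run_all(file.path(fixture_dir(), "config.yaml"))
  }
  fixture_env$report
}
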