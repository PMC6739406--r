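# Seeded generators for every input table the pipeline consumes, plus a
# deterministic reference fixture bundle. All coordinates are on a toy
# "chrX" of a few Mb: only the containment topology and the identities of
# the known host-gene/miRNA relations are preserved, not real assembly
# coordinates. All randomness flows from the explicit `seed` argument.

#' The eight apoptosis-pathway targets of miR-548am-5p
#'
#' Validated miR-548am-5p target genes annotated to the KEGG apoptosis
#' pathway, used to anchor the synthetic target table and pathway sets.
#' @export
APOPTOSIS_GENES <- c("APAF1", "ATM", "BAX", "CAPN2", "PIK3R1", "PRKAR2B",
                     "TNFRSF10B", "XIAP")

#' The known escaper-host to miRNA map on chrX
#'
#' Six XCI-escaper genes and the twelve miRNA precursor loci contained in
#' their gene bodies; the topology the annotation fixture reproduces.
#' @export
HOST_MIR_MAP <- list(
  CSF2RA = "hsa-miR-3690",
  CTPS2 = "hsa-miR-548am",
  GABRE = c("hsa-miR-224", "hsa-miR-452"),
  HTR2C = c("hsa-miR-1264", "hsa-miR-1298", "hsa-miR-1911",
            "hsa-miR-1912", "hsa-miR-448", "hsa-miR-764"),
  PUDP = "hsa-miR-4767",
  VGLL1 = "hsa-miR-934"
)

#' Generate escape-call tables and a symbol map
#'
#' Emulates two escape-call studies: a hybrid-line table (carrel dialect)
#' whose escapers normalize to exactly `n_escape_a` approved symbols, an
#' allelic-ratio table (cotton dialect) normalizing to exactly
#' `n_escape_b`, with exactly `n_overlap` symbols shared. Raw identifier
#' lists exceed the valid counts: they contain alias duplicates, withdrawn
#' identifiers and unmatched junk so that symbol normalization is
#' exercised (with defaults, 99 raw escaper IDs collapse to 64 in the
#' carrel table and 68 to 65 in the cotton table). When
#' `anchor_genes = TRUE` the sets contain the six known chrX host genes
#' with their known dataset membership, and PUDP enters the carrel raw
#' list under its previous symbol HDHD1.
#'
#' @param dir Output directory (created if missing).
#' @param n_escape_a,n_escape_b,n_overlap Post-normalization escaper set
#'   sizes and their intersection.
#' @param n_inactivated,n_variable Numbers of XCI-subject and
#'   variable-escape genes added to the tables.
#' @param n_lines Hybrid-line panel size (default 9).
#' @param extras_a,extras_b Named vectors `c(dup=, withdrawn=, unmatched=)`
#'   of extra raw rows per table.
#' @param anchor_genes Include the six known host genes (requires
#'   `n_overlap >= 1`, `n_escape_a - n_overlap >= 1`,
#'   `n_escape_b - n_overlap >= 4`).
#' @param seed Integer seed; identical arguments and seed give
#'   byte-identical files.
#' @return Invisibly, a list with `paths` (carrel, cotton, symbol_map) and
#'   `truth` (the planted sets).
#' @export
gen_escape_tables <- function(dir, n_escape_a = 64L, n_escape_b = 65L,
                              n_overlap = 23L, n_inactivated = 20L,
                              n_variable = 10L, n_lines = 9L,
                              extras_a = c(dup = 15L, withdrawn = 10L, unmatched = 10L),
                              extras_b = c(dup = 1L, withdrawn = 1L, unmatched = 1L),
                              anchor_genes = TRUE, seed = 1L) {
  if (n_overlap > min(n_escape_a, n_escape_b)) {
    stop("n_overlap cannot exceed min(n_escape_a, n_escape_b)", call. = FALSE)
  }
  if (any(c(n_escape_a, n_escape_b, n_overlap, n_inactivated, n_variable) < 0)) {
    stop("all set sizes must be non-negative", call. = FALSE)
  }
  if (anchor_genes &&
      (n_overlap < 1L || n_escape_a - n_overlap < 1L || n_escape_b - n_overlap < 4L)) {
    stop("anchor_genes = TRUE needs n_overlap >= 1, |A only| >= 1 and |B only| >= 4",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  pad <- function(prefix, anchors, n) {
    extra <- n - length(anchors)
    c(anchors, if (extra > 0) sprintf("%s%03d", prefix, seq_len(extra)))
  }
  common <- pad("ESCC", if (anchor_genes) "PUDP" else character(), n_overlap)
  a_only <- pad("ESCA", if (anchor_genes) "CTPS2" else character(),
                n_escape_a - n_overlap)
  b_only <- pad("ESCB",
                if (anchor_genes) c("CSF2RA", "GABRE", "HTR2C", "VGLL1") else character(),
                n_escape_b - n_overlap)
  set_a <- c(common, a_only)
  set_b <- c(common, b_only)
  inact <- if (n_inactivated > 0) sprintf("XIG%03d", seq_len(n_inactivated)) else character()
  varg <- if (n_variable > 0) sprintf("VARG%03d", seq_len(n_variable)) else character()

  cap <- function(x, n) min(as.integer(x), as.integer(n))
  dup_a <- cap(extras_a[["dup"]], length(set_a))
  dup_b <- cap(extras_b[["dup"]], length(set_b))

  map <- tibble::tibble(
    input_id = c(set_a, set_b, inact, varg) |> unique(),
    status = "approved"
  )
  map$approved_symbol <- map$input_id
  alias_rows <- tibble::tibble(
    input_id = c(if (dup_a > 0) sprintf("ALSA%03d", seq_len(dup_a)),
                 if (dup_b > 0) sprintf("ALSB%03d", seq_len(dup_b))),
    status = "alias",
    approved_symbol = c(utils::head(set_a, dup_a), utils::head(set_b, dup_b))
  )
  wdn_a <- as.integer(extras_a[["withdrawn"]])
  wdn_b <- as.integer(extras_b[["withdrawn"]])
  wdn_rows <- tibble::tibble(
    input_id = c(if (wdn_a > 0) sprintf("WDNA%03d", seq_len(wdn_a)),
                 if (wdn_b > 0) sprintf("WDNB%03d", seq_len(wdn_b))),
    status = "withdrawn",
    approved_symbol = NA_character_
  )
  prev_rows <- if (anchor_genes) {
    tibble::tibble(input_id = "HDHD1", status = "previous",
                   approved_symbol = "PUDP")
  } else NULL
  symbol_map <- dplyr::bind_rows(map, alias_rows, wdn_rows, prev_rows)

  # raw escaper identifier lists: base rows (one per gene, PUDP as HDHD1 in
  # the carrel list), plus alias duplicates, withdrawn and unmatched junk
  raw_a <- set_a
  if (anchor_genes) raw_a[raw_a == "PUDP"] <- "HDHD1"
  raw_a <- c(raw_a,
             if (dup_a > 0) sprintf("ALSA%03d", seq_len(dup_a)),
             if (wdn_a > 0) sprintf("WDNA%03d", seq_len(wdn_a)),
             if (extras_a[["unmatched"]] > 0)
               sprintf("UNKA%03d", seq_len(extras_a[["unmatched"]])))
  raw_b <- c(set_b,
             if (dup_b > 0) sprintf("ALSB%03d", seq_len(dup_b)),
             if (wdn_b > 0) sprintf("WDNB%03d", seq_len(wdn_b)),
             if (extras_b[["unmatched"]] > 0)
               sprintf("UNKB%03d", seq_len(extras_b[["unmatched"]])))

  withr::with_seed(seed, {
    carrel <- dplyr::bind_rows(
      tibble::tibble(gene_id = raw_a,
                     n_expressing = sample(7:n_lines, length(raw_a), replace = TRUE)),
      tibble::tibble(gene_id = inact,
                     n_expressing = sample(0:2, length(inact), replace = TRUE)),
      tibble::tibble(gene_id = varg,
                     n_expressing = sample(3:6, length(varg), replace = TRUE))
    )
    carrel$n_lines <- n_lines
    carrel <- carrel[sample.int(nrow(carrel)), , drop = FALSE]

    low_ratio_genes <- c(inact, varg, a_only)
    cotton <- dplyr::bind_rows(
      tibble::tibble(gene_id = raw_b,
                     xi_xa_ratio = round(runif(length(raw_b), 0.12, 0.95), 3)),
      tibble::tibble(gene_id = low_ratio_genes,
                     xi_xa_ratio = round(runif(length(low_ratio_genes), 0, 0.09), 3))
    )
    cotton <- cotton[sample.int(nrow(cotton)), , drop = FALSE]
  })

  paths <- list(
    carrel = file.path(dir, "carrel_calls.tsv"),
    cotton = file.path(dir, "cotton_calls.tsv"),
    symbol_map = file.path(dir, "symbol_map.tsv")
  )
  readr::write_tsv(carrel, paths$carrel, progress = FALSE)
  readr::write_tsv(cotton, paths$cotton, progress = FALSE)
  readr::write_tsv(symbol_map, paths$symbol_map, progress = FALSE)
  invisible(list(paths = paths,
                 truth = list(set_a = set_a, set_b = set_b, common = common,
                              inactivated = inact, variable = varg)))
}

#' Generate gene and miRNA annotation GFF3 files
#'
#' Lays out gene loci in non-overlapping slots on a toy chromosome and
#' places each specified hosted miRNA strictly inside its host's interval
#' on the same strand. Decoy miRs are placed in intergenic space. Before
#' writing, the intended containment topology is verified with a
#' brute-force all-pairs check; generation fails if any unintended
#' containment exists.
#'
#' @param dir Output directory.
#' @param hosting Named list gene -> character vector of hosted miR IDs
#'   (default [HOST_MIR_MAP]).
#' @param control_hosting Like `hosting`, for XCI-subject loci hosting
#'   negative-control miRs.
#' @param other_genes Additional gene symbols placed without any hosted miR.
#' @param n_decoys Number of intergenic decoy miR loci (default 60).
#' @param chrom Chromosome name.
#' @param seed Integer seed (strand jitter of decoys).
#' @return Invisibly, a list with `paths` (genes, mirs) and `truth`
#'   (expected hosting pairs as a tibble `gene`, `mir`).
#' @export
gen_annotation <- function(dir, hosting = HOST_MIR_MAP,
                           control_hosting = list(), other_genes = character(),
                           n_decoys = 60L, chrom = "chrX", seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_hosting <- c(hosting, control_hosting)
  gene_ids <- c(names(all_hosting), other_genes)
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene identifiers in the annotation spec", call. = FALSE)
  }
  slot_w <- 60000L
  gene_w <- 40000L
  max_per_gene <- (gene_w - 4000L) %/% 3000L
  too_many <- vapply(all_hosting, length, integer(1)) > max_per_gene
  if (any(too_many)) {
    stop("too many hosted miRs for one gene slot: ",
         paste(names(all_hosting)[too_many], collapse = ", "), call. = FALSE)
  }

  n_genes <- length(gene_ids)
  gstart <- 50001L + (seq_len(n_genes) - 1L) * slot_w
  genes <- tibble::tibble(
    feature_id = gene_ids,
    kind = "gene",
    chrom = chrom,
    start = gstart,
    end = gstart + gene_w - 1L,
    strand = rep(c("+", "-"), length.out = n_genes)
  )

  hosted <- NULL
  if (length(all_hosting) > 0) {
    hosted <- dplyr::bind_rows(lapply(seq_along(all_hosting), function(i) {
      ms <- all_hosting[[i]]
      if (length(ms) == 0) return(NULL)
      s <- gstart[i] + 2000L + (seq_along(ms) - 1L) * 3000L
      tibble::tibble(feature_id = ms, kind = "mirna", chrom = chrom,
                     start = s, end = s + 79L,
                     strand = genes$strand[i])
    }))
  }

  # decoys go in the intergenic tail of each slot, then past the last slot
  decoys <- NULL
  if (n_decoys > 0) {
    per_gap <- 10L
    gap_starts <- gstart + gene_w + 2000L
    pos <- integer(0)
    for (g in gap_starts) {
      pos <- c(pos, g + (seq_len(per_gap) - 1L) * 500L)
      if (length(pos) >= n_decoys) break
    }
    if (length(pos) < n_decoys) {
      tail_start <- if (n_genes > 0) gstart[n_genes] + slot_w + 2000L else 50001L
      pos <- c(pos, tail_start + (seq_len(n_decoys - length(pos)) - 1L) * 500L)
    }
    pos <- pos[seq_len(n_decoys)]
    decoys <- withr::with_seed(seed, tibble::tibble(
      feature_id = sprintf("hsa-miR-9%03d", seq_len(n_decoys)),
      kind = "mirna", chrom = chrom,
      start = pos, end = pos + 79L,
      strand = sample(c("+", "-"), n_decoys, replace = TRUE)
    ))
  }
  mirs <- dplyr::bind_rows(hosted, decoys)

  # brute-force verification of the intended containment topology
  intended <- if (length(all_hosting) > 0) {
    dplyr::bind_rows(lapply(names(all_hosting), function(g) {
      if (length(all_hosting[[g]]) == 0) return(NULL)
      tibble::tibble(gene = g, mir = all_hosting[[g]])
    }))
  } else {
    tibble::tibble(gene = character(), mir = character())
  }
  actual <- brute_force_containment(genes, mirs)
  if (!setequal(paste(actual$gene, actual$mir),
                paste(intended$gene, intended$mir))) {
    stop("internal error: generated annotation does not reproduce the ",
         "requested containment topology", call. = FALSE)
  }

  paths <- list(genes = file.path(dir, "genes.gff3"),
                mirs = file.path(dir, "mirs.gff3"))
  write_gff3(genes, paths$genes)
  write_gff3(mirs, paths$mirs)
  invisible(list(paths = paths,
                 truth = list(pairs = intended, genes = genes, mirs = mirs)))
}

#' @noRd
brute_force_containment <- function(genes, mirs) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(mirs))) {
      if (genes$chrom[i] == mirs$chrom[j] &&
          genes$start[i] <= mirs$start[j] && mirs$end[j] <= genes$end[i]) {
        out[[length(out) + 1L]] <- tibble::tibble(gene = genes$feature_id[i],
                                                  mir = mirs$feature_id[j])
      }
    }
  }
  if (length(out) == 0) return(tibble::tibble(gene = character(), mir = character()))
  dplyr::bind_rows(out)
}

#' Generate a tissue escape table
#'
#' Writes the specified per-gene (expressed, logFC) records for one tissue,
#' plus seeded random records for any additional genes.
#'
#' @param dir Output directory.
#' @param spec Tibble with columns `gene`, `expressed`, `logfc`.
#' @param tissue Tissue name for all rows (default `"fibroblast"`).
#' @param other_genes Genes given random expressed/logfc records.
#' @param seed Integer seed.
#' @return Invisibly, the output path.
#' @export
gen_tissue_table <- function(dir, spec, tissue = "fibroblast",
                             other_genes = character(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- tibble::tibble(gene = spec$gene, tissue = tissue,
                         expressed = spec$expressed, logfc = spec$logfc)
  if (length(other_genes) > 0) {
    rows <- withr::with_seed(seed, dplyr::bind_rows(rows, tibble::tibble(
      gene = other_genes, tissue = tissue,
      expressed = runif(length(other_genes)) < 0.7,
      logfc = round(rnorm(length(other_genes), 0, 0.8), 3)
    )))
    rows$logfc[!rows$expressed & rows$gene %in% other_genes] <- NA_real_
  }
  path <- file.path(dir, "tissue_escape.tsv")
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' @noRd
mir_slug <- function(mir_id) {
  gsub("[^A-Za-z0-9]", "", toupper(sub("^hsa-", "", mir_id)))
}

#' Generate a miRNA-target interaction table
#'
#' Each miR receives exactly its specified target count. A spec entry may
#' be an integer (that many deterministic synthetic symbols), a character
#' vector (used verbatim), or `list(n =, include =)` (the named genes
#' padded with synthetic symbols up to `n`).
#'
#' @param dir Output directory.
#' @param target_spec Named list, miR ID -> spec entry.
#' @param seed Integer seed (row shuffling).
#' @return Invisibly, the output path.
#' @export
gen_target_db <- function(dir, target_spec, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- dplyr::bind_rows(lapply(names(target_spec), function(mir) {
    entry <- target_spec[[mir]]
    if (is.numeric(entry)) entry <- list(n = entry, include = character())
    if (is.character(entry)) entry <- list(n = length(entry), include = entry)
    n_extra <- entry$n - length(entry$include)
    if (n_extra < 0) stop("include list longer than n for ", mir, call. = FALSE)
    genes <- c(entry$include,
               if (n_extra > 0) sprintf("T%s%04d", mir_slug(mir), seq_len(n_extra)))
    tibble::tibble(mir_id = mir, gene = genes, evidence = "synthetic")
  }))
  rows <- withr::with_seed(seed, rows[sample.int(nrow(rows)), , drop = FALSE])
  path <- file.path(dir, "targets.tsv")
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Generate pathway gene sets with one planted enrichment
#'
#' Builds a GMT whose background (union of members) contains the planted
#' hit genes and a thin scatter of `shared_targets` across decoy sets, so
#' that a query holding all hits plus the shared targets over-represents
#' the planted set with an analytically known hypergeometric p while the
#' decoys sit at their null expectation.
#'
#' @param dir Output directory.
#' @param planted `list(name =, hits =)`: the enriched set and the query
#'   genes placed in it.
#' @param shared_targets Query genes distributed round-robin over decoys.
#' @param n_decoy_sets Number of decoy sets.
#' @param set_size Genes per set.
#' @param seed Integer seed (unused filler is deterministic; kept for API
#'   symmetry).
#' @return Invisibly, the output path.
#' @export
gen_pathways <- function(dir, planted = list(name = "APOPTOSIS", hits = APOPTOSIS_GENES),
                         shared_targets = character(), n_decoy_sets = 9L,
                         set_size = 40L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(planted$hits) > set_size) {
    stop("planted hit list exceeds set_size", call. = FALSE)
  }
  n_fill <- (set_size - length(planted$hits)) +
    n_decoy_sets * set_size - length(shared_targets)
  filler <- sprintf("BGF%04d", seq_len(n_fill))
  fi <- 0L
  take <- function(n) {
    out <- filler[fi + seq_len(n)]
    fi <<- fi + n
    out
  }
  sets <- list()
  sets[[planted$name]] <- c(planted$hits, take(set_size - length(planted$hits)))
  slices <- if (length(shared_targets) > 0 && n_decoy_sets > 0) {
    split(shared_targets, rep(seq_len(n_decoy_sets),
                              length.out = length(shared_targets)))
  } else list()
  for (d in seq_len(n_decoy_sets)) {
    sl <- if (d <= length(slices)) slices[[d]] else character()
    sets[[sprintf("DECOY_PATHWAY_%02d", d)]] <- c(sl, take(set_size - length(sl)))
  }
  path <- file.path(dir, "pathways.gmt")
  write_gmt(sets, path)
  invisible(path)
}

#' Plant an exact enrichment configuration
#'
#' Builds a background of `N` genes, one gene set of size `K` and a query
#' of size `n` overlapping the set in exactly `k` genes, so the expected
#' upper-tail hypergeometric p-value is analytically known.
#'
#' @param N,K,n,k Background size, set size, query size, overlap.
#' @return A list with `query`, `sets` (named list of one set) and
#'   `background`.
#' @export
gen_planted_enrichment <- function(N, K, n, k) {
  if (K > N || n > N) stop("K and n cannot exceed N", call. = FALSE)
  if (k > min(K, n) || k < max(0L, n + K - N)) {
    stop("overlap k is infeasible for (N, K, n)", call. = FALSE)
  }
  background <- sprintf("G%04d", seq_len(N))
  set <- background[seq_len(K)]
  query <- c(background[seq_len(k)],
             if (n - k > 0) background[K + seq_len(n - k)])
  list(query = query, sets = list(PLANTED = set), background = background)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates a two-group TaqMan experiment: reference assays fluctuate
#' around fixed base levels, the target assay is shifted by
#' `-log2(true_fold)` cycles in the test group, control assays carry no
#' shift. Per-sample baselines (biological variation) and per-replicate
#' Normal(0, sigma) noise are added; with `sigma = 0` the 2^-ddCt estimate
#' recovers `true_fold` exactly.
#'
#' @param true_fold Planted test/calibrator expression fold (> 0).
#' @param sigma Replicate noise SD in cycles (>= 0).
#' @param n_per_group Samples per group.
#' @param n_replicates Technical replicates per (sample, assay).
#' @param seed Integer seed.
#' @param target_assay,reference_assays,control_assays Assay names.
#' @param group_test,group_calibrator Group labels.
#' @param path Optional output TSV path.
#' @return The replicate-level Ct tibble (written to `path` when given).
#' @export
gen_qpcr <- function(true_fold = 5, sigma = 0.2, n_per_group = 8L,
                     n_replicates = 3L, seed = 1L,
                     target_assay = "hsa-miR-548am-5p",
                     reference_assays = c("RNU6B", "RNU44"),
                     control_assays = character(),
                     group_test = "XX", group_calibrator = "XY",
                     path = NULL) {
  if (true_fold <= 0) stop("true_fold must be > 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (n_per_group < 1 || n_replicates < 1) {
    stop("n_per_group and n_replicates must be >= 1", call. = FALSE)
  }
  assays <- c(target_assay, reference_assays, control_assays)
  base <- c(26, 20 + seq_along(reference_assays) - 1,
            if (length(control_assays) > 0) 24 + seq_along(control_assays) - 1)
  names(base) <- assays
  groups <- c(rep(group_test, n_per_group), rep(group_calibrator, n_per_group))
  sample_ids <- c(sprintf("%s%02d", group_test, seq_len(n_per_group)),
                  sprintf("%s%02d", group_calibrator, seq_len(n_per_group)))
  out <- withr::with_seed(seed, {
    baseline <- rnorm(length(sample_ids), 0, 0.4)
    grid <- expand.grid(si = seq_along(sample_ids), assay = assays,
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    shift <- ifelse(grid$assay == target_assay & groups[grid$si] == group_test,
                    -log2(true_fold), 0)
    tibble::tibble(
      sample_id = sample_ids[grid$si],
      group = groups[grid$si],
      assay = grid$assay,
      replicate = as.integer(grid$replicate),
      ct = base[grid$assay] + baseline[grid$si] + shift +
        rnorm(nrow(grid), 0, sigma)
    )
  })
  out <- dplyr::arrange(out, .data$sample_id, .data$assay, .data$replicate)
  if (!is.null(path)) readr::write_tsv(out, path, progress = FALSE)
  out
}

#' Write the deterministic reference fixture bundle
#'
#' Generates, with a frozen default seed, a complete and mutually
#' consistent input bundle that encodes the known chrX escaper/miRNA
#' relations: escaper sets of sizes 64 and 65 sharing 23 symbols (union
#' 106); the six host genes containing twelve miR loci plus 60 intergenic
#' decoys; a fibroblast escape table in which CSF2RA, HTR2C and VGLL1 are
#' not expressed, GABRE has a negative log fold change, and CTPS2 and PUDP
#' escape; a target table giving miR-548am-5p 332 validated targets
#' (including the eight apoptosis genes) and miR-4767 three; pathway sets
#' with apoptosis planted as the single enriched set; XCI-subject loci
#' hosting the negative controls miR-548ax and miR-23c; and a qPCR table
#' with a planted 5-fold XX/XY difference for miR-548am-5p. A
#' `config.yaml` (relative paths) and a `manifest.json` of expected
#' downstream counts are written alongside.
#'
#' @param dir Output directory.
#' @param seed Integer master seed (default frozen at 20090; sub-seeds are
#'   derived per generator). The planted relations and all downstream
#'   counts are seed-invariant; the seed only moves noise and row order.
#' @return Invisibly, a list with `dir`, `paths` and `manifest`.
#' @export
fixture_bundle <- function(dir, seed = 20090L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  esc <- gen_escape_tables(dir, seed = seed + 1L)
  truth <- esc$truth
  union_genes <- union(truth$set_a, truth$set_b)

  control_hosting <- list(XIG001 = "hsa-miR-548ax", XIG002 = "hsa-miR-23c")
  placed <- c(names(HOST_MIR_MAP), names(control_hosting))
  ann <- gen_annotation(
    dir, hosting = HOST_MIR_MAP, control_hosting = control_hosting,
    other_genes = setdiff(c(union_genes, truth$inactivated, truth$variable), placed),
    n_decoys = 60L, seed = seed + 2L
  )

  tissue_spec <- tibble::tibble(
    gene = c("CSF2RA", "HTR2C", "VGLL1", "GABRE", "CTPS2", "PUDP"),
    expressed = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    logfc = c(NA, NA, NA, -0.45, 0.35, 0.52)
  )
  tissue_path <- gen_tissue_table(
    dir, tissue_spec, tissue = "fibroblast",
    other_genes = setdiff(union_genes, tissue_spec$gene), seed = seed + 3L
  )

  shared_targets <- sprintf("BGT%04d", 1:12)
  targets_path <- gen_target_db(dir, list(
    "hsa-miR-548am-5p" = list(n = 332L, include = c(APOPTOSIS_GENES, shared_targets)),
    "hsa-miR-548am-3p" = 20L,
    "hsa-miR-4767" = 3L,
    "hsa-miR-548ax" = 15L,
    "hsa-miR-23c" = 10L
  ), seed = seed + 4L)

  gmt_path <- gen_pathways(dir, planted = list(name = "APOPTOSIS", hits = APOPTOSIS_GENES),
                           shared_targets = shared_targets,
                           n_decoy_sets = 9L, set_size = 40L, seed = seed + 5L)

  qpcr_path <- file.path(dir, "qpcr_ct.tsv")
  gen_qpcr(true_fold = 5, sigma = 0.2, n_per_group = 8L, n_replicates = 3L,
           seed = seed + 6L,
           control_assays = c("hsa-miR-23c", "hsa-miR-548ax"),
           path = qpcr_path)

  config <- list(
    paths = list(
      carrel = basename(esc$paths$carrel),
      cotton = basename(esc$paths$cotton),
      symbol_map = basename(esc$paths$symbol_map),
      genes_gff3 = basename(ann$paths$genes),
      mirs_gff3 = basename(ann$paths$mirs),
      tissue_table = basename(tissue_path),
      targets = basename(targets_path),
      pathways_gmt = basename(gmt_path),
      qpcr = basename(qpcr_path)
    ),
    params = list(
      escape_min = 7L, inactive_max = 2L, ratio_min = 0.10,
      strand_policy = "same", tissue = "fibroblast",
      pathway = "APOPTOSIS", alpha = 0.05, min_targets = 10L,
      fold_threshold = 1.5,
      target_assay = "hsa-miR-548am-5p",
      reference_assays = c("RNU6B", "RNU44"),
      group_test = "XX", group_calibrator = "XY"
    )
  )
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)

  manifest <- list(
    synthetic = TRUE,
    seed = seed,
    expected = list(
      n_escape_a = length(truth$set_a),
      n_escape_b = length(truth$set_b),
      n_intersection = length(intersect(truth$set_a, truth$set_b)),
      n_union = length(union_genes),
      n_host_genes = length(HOST_MIR_MAP),
      n_hosting_pairs = length(unlist(HOST_MIR_MAP)),
      tissue_retained = c("CTPS2", "PUDP"),
      n_targets_mir548am_5p = 332L,
      n_targets_mir4767 = 3L,
      apoptosis_overlap = length(APOPTOSIS_GENES),
      control_mirs = c("hsa-miR-548ax", "hsa-miR-23c"),
      top_candidate = "hsa-miR-548am-5p",
      qpcr_true_fold = 5
    )
  )
  manifest_path <- file.path(dir, "manifest.json")
  write_report(manifest, manifest_path, format = "json")

  invisible(list(dir = dir,
                 paths = c(esc$paths,
                           ann$paths,
                           list(tissue = tissue_path, targets = targets_path,
                                pathways = gmt_path, qpcr = qpcr_path,
                                config = config_path, manifest = manifest_path)),
                 manifest = manifest))
}
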