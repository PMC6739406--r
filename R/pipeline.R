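# Run configuration and the end-to-end pipeline driver.

DEFAULT_PARAMS <- list(
  escape_min = 7L, inactive_max = 2L, ratio_min = 0.10,
  strand_policy = "same", tissue = "fibroblast",
  pathway = "APOPTOSIS", alpha = 0.05, min_targets = 10L,
  fold_threshold = 1.5,
  target_assay = NULL,
  reference_assays = c("RNU6B", "RNU44"),
  group_test = "XX", group_calibrator = "XY"
)

#' Load and validate a run configuration
#'
#' A configuration names the input tables (`paths`) and the stage
#' parameters (`params`); unspecified parameters take documented defaults.
#' Relative paths are resolved against the YAML file's directory (or
#' `base_dir` for list input). Validation checks that every referenced
#' file exists and that thresholds lie in their documented ranges.
#'
#' @param config Path to a YAML file, or a list with elements `paths` and
#'   `params`.
#' @param base_dir Directory against which relative paths are resolved when
#'   `config` is a list.
#' @return A validated config list of class `xci_run_config`.
#' @export
load_run_config <- function(config, base_dir = ".") {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  paths <- config$paths
  required <- c("carrel", "cotton", "symbol_map", "genes_gff3", "mirs_gff3",
                "tissue_table", "targets", "pathways_gmt")
  missing <- setdiff(required, names(paths))
  if (length(missing) > 0) {
    stop("config is missing input path(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base_dir, p)
    p
  }
  paths <- lapply(paths, resolve)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]])) {
      stop("config input '", nm, "' does not exist: ", paths[[nm]], call. = FALSE)
    }
  }
  params <- utils::modifyList(DEFAULT_PARAMS, config$params %||% list())
  stopifnot(
    "escape_min must exceed inactive_max" = params$escape_min > params$inactive_max,
    "inactive_max must be >= 0" = params$inactive_max >= 0,
    "ratio_min must be > 0" = params$ratio_min > 0,
    "alpha must be in (0, 1]" = params$alpha > 0 && params$alpha <= 1,
    "fold_threshold must be >= 1" = params$fold_threshold >= 1,
    "strand_policy must be 'same' or 'ignore'" =
      params$strand_policy %in% c("same", "ignore")
  )
  structure(list(paths = paths, params = params), class = "xci_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
mature_ids <- function(precursor, interactions) {
  ids <- unique(interactions$mir_id)
  sort(ids[ids == precursor | startsWith(ids, paste0(precursor, "-"))])
}

#' Run the full discovery pipeline
#'
#' Chains every stage on the configured inputs:
#' escape classification and symbol normalization in both dialects ->
#' set reconciliation -> miRNA host-gene containment mapping over the
#' escaper union -> tissue escape filter -> negative-control selection ->
#' validated-target extraction with pathway over-representation testing ->
#' candidate ranking -> (when Ct data are configured) 2^-ddCt
#' quantification. Host-gene candidates carry precursor miR IDs; target
#' lookup expands each precursor to the mature arm IDs present in the
#' interaction table.
#'
#' @param config An `xci_run_config` (or anything [load_run_config()]
#'   accepts).
#' @param out_dir Optional directory: writes `report.json`, `ranking.tsv`
#'   and the fully resolved `config_resolved.yaml`.
#' @return A list of class `xci_pipeline_report` with per-stage results and
#'   counts.
#' @export
run_all <- function(config, out_dir = NULL) {
  if (!inherits(config, "xci_run_config")) config <- load_run_config(config)
  p <- config$paths
  prm <- config$params

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- escape classification and reconciliation -------------------------
  rec <- stage("escape_reconcile", {
    carrel <- classify_carrel(read_escape_table(p$carrel, "carrel"),
                              prm$escape_min, prm$inactive_max)
    cotton <- classify_cotton(read_escape_table(p$cotton, "cotton"),
                              prm$ratio_min)
    symbol_map <- read_symbol_map(p$symbol_map)
    norm_a <- normalize_symbols(carrel$gene_id[carrel$category == "escape"], symbol_map)
    norm_b <- normalize_symbols(cotton$gene_id[cotton$category == "escape"], symbol_map)
    mapping_log <- dplyr::bind_rows(
      dplyr::mutate(norm_a$log, dataset = "carrel"),
      dplyr::mutate(norm_b$log, dataset = "cotton")
    )
    rec <- reconcile(norm_a$symbols, norm_b$symbols, mapping_log)

    # genes inactivated in every dataset where they are called, and not
    # escapers anywhere: the XCI-subject loci used for negative controls
    cat_by_gene <- function(calls, map) {
      nm <- normalize_symbols(calls$gene_id, map)
      tibble::tibble(gene = nm$log$approved_symbol, category = calls$category) |>
        dplyr::filter(!is.na(.data$gene))
    }
    cats <- dplyr::bind_rows(cat_by_gene(carrel, symbol_map),
                             cat_by_gene(cotton, symbol_map))
    inact <- cats |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(all_inact = all(.data$category == "inactivated"),
                       .groups = "drop") |>
      dplyr::filter(.data$all_inact)
    list(reconcile = rec, inactivated = setdiff(inact$gene, rec$union))
  })

  # -- host mapping ------------------------------------------------------
  hosting <- stage("mir_hosting", {
    genes <- read_gff3(p$genes_gff3, kind_filter = "gene")
    mirs <- read_gff3(p$mirs_gff3, kind_filter = "mirna")
    escaper_genes <- genes[genes$feature_id %in% rec$reconcile$union, , drop = FALSE]
    pairs <- map_hosted_mirs(escaper_genes, mirs, strand_policy = prm$strand_policy)
    list(pairs = pairs, genes = genes, mirs = mirs,
         n_host_genes = length(unique(pairs$gene)),
         n_pairs = nrow(pairs))
  })

  # -- tissue filter -----------------------------------------------------
  tissue <- stage("tissue_filter", {
    tab <- read_tissue_table(p$tissue_table)
    filter_tissue_escape(unique(hosting$pairs$gene), tab, prm$tissue)
  })

  # -- negative controls -------------------------------------------------
  controls <- stage("control_selection", {
    inact_genes <- hosting$genes[hosting$genes$feature_id %in% rec$inactivated, ,
                                 drop = FALSE]
    candidate_precursors <- unique(
      hosting$pairs$mir[hosting$pairs$gene %in% tissue$retained])
    select_control_mirs(hosting$mirs, unique(hosting$pairs$mir), inact_genes,
                        k = 2L, candidate_mirs = candidate_precursors)
  })

  # -- targets and enrichment -------------------------------------------
  enr <- stage("target_enrichment", {
    interactions <- read_targets(p$targets)
    gene_sets <- read_gmt(p$pathways_gmt)
    background <- unique(unlist(gene_sets, use.names = FALSE))
    retained_pairs <- hosting$pairs[hosting$pairs$gene %in% tissue$retained, ,
                                    drop = FALSE]
    cand_rows <- list()
    enr_rows <- list()
    for (i in seq_len(nrow(retained_pairs))) {
      prec <- retained_pairs$mir[i]
      for (mid in mature_ids(prec, interactions)) {
        targets <- get_targets(mid, interactions)
        e <- hypergeom_enrich(intersect(targets, background), gene_sets, background)
        e$mir_id <- mid
        enr_rows[[mid]] <- e
        cand_rows[[mid]] <- tibble::tibble(
          mir_id = mid, host_gene = retained_pairs$gene[i],
          tissue_supported = TRUE, n_targets = length(targets)
        )
      }
    }
    list(candidates = dplyr::bind_rows(cand_rows),
         enrichments = dplyr::bind_rows(enr_rows),
         background_size = length(background))
  })

  ranking <- stage("prioritize", {
    prioritize(enr$candidates, enr$enrichments, prm$pathway,
               alpha = prm$alpha, min_targets = prm$min_targets)
  })

  # -- optional validation quantification -------------------------------
  qpcr <- NULL
  if (!is.null(p$qpcr)) {
    qpcr <- stage("validation_quant", {
      samples <- read_qpcr(p$qpcr)
      target <- prm$target_assay %||%
        (if (nrow(ranking) > 0) ranking$mir_id[1] else NULL)
      if (is.null(target)) NULL else {
        assays <- c(target, intersect(controls, unique(samples$assay)))
        lapply(setNames(assays, assays), function(a) {
          delta_delta_ct(samples, a, prm$reference_assays,
                         prm$group_test, prm$group_calibrator,
                         prm$fold_threshold)
        })
      }
    })
  }

  report <- structure(list(
    escape = list(
      sizes = rec$reconcile$sizes,
      intersection = rec$reconcile$intersection,
      union = rec$reconcile$union,
      inactivated = rec$inactivated
    ),
    hosting = list(
      n_host_genes = hosting$n_host_genes,
      n_pairs = hosting$n_pairs,
      pairs = hosting$pairs
    ),
    tissue = list(
      tissue = prm$tissue,
      retained = tissue$retained,
      exclusions = tissue$exclusions
    ),
    controls = controls,
    enrichment = list(
      background_size = enr$background_size,
      results = enr$enrichments
    ),
    ranking = ranking,
    qpcr = qpcr,
    params = prm,
    version = as.character(utils::packageVersion("xcimir")),
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "xci_pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    json_report <- report
    json_report$ranking$enriched_sets <- NULL
    json_report$qpcr <- lapply(json_report$qpcr, function(x) {
      x$per_sample <- NULL
      unclass(x)
    })
    write_report(unclass_deep(unclass(json_report)),
                 file.path(out_dir, "report.json"), "json")
    write_report(dplyr::select(ranking, -"enriched_sets"),
                 file.path(out_dir, "ranking.tsv"), "tsv")
    yaml::write_yaml(list(paths = p, params = prm),
                     file.path(out_dir, "config_resolved.yaml"))
  }
  report
}

#' @export
print.xci_pipeline_report <- function(x, ...) {
  cat("XCI-escaper miRNA discovery report\n")
  s <- x$escape$sizes
  cat(sprintf("  escaper sets: |A| = %d, |B| = %d, intersection = %d, union = %d\n",
              s$set_a, s$set_b, s$intersection, s$union))
  cat(sprintf("  host mapping: %d hosting pairs across %d escaper genes\n",
              x$hosting$n_pairs, x$hosting$n_host_genes))
  cat(sprintf("  %s filter: %d retained (%s)\n", x$tissue$tissue,
              length(x$tissue$retained), paste(x$tissue$retained, collapse = ", ")))
  cat(sprintf("  negative controls: %s\n", paste(x$controls, collapse = ", ")))
  if (nrow(x$ranking) > 0) {
    cat(sprintf("  top candidate: %s (host %s, %d targets)\n",
                x$ranking$mir_id[1], x$ranking$host_gene[1], x$ranking$n_targets[1]))
  }
  for (fc in x$qpcr) {
    cat(sprintf("  qPCR %s: fold = %.3f (%ssignificant)\n",
                fc$assay, fc$fold, if (fc$significant) "" else "not "))
  }
  invisible(x)
}
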