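# Interval-containment mapping of miRNA loci into host genes, the
# tissue-specific escape filter, and negative-control miR selection.

#' Map miRNA loci into host gene bodies
#'
#' A gene "hosts" a miRNA when the miRNA locus lies fully inside the gene's
#' genomic interval on the same chromosome (boundaries inclusive; an
#' interval equal to the gene interval counts as hosted). Containment, not
#' mere overlap: intragenic miRs are typically co-transcribed with their
#' host, which is the biological premise of the pipeline. A miR contained in
#' several (e.g. nested) genes yields one pair per containing gene.
#'
#' miR features are precursor (stem-loop) loci; mature -5p/-3p arms are name
#' suffixes downstream, not separate intervals.
#'
#' @param genes Feature tibble (kind `gene`), e.g. restricted to the escaper
#'   candidate set.
#' @param mirs Feature tibble (kind `mirna`).
#' @param strand_policy `"same"` (default; a feature of unknown strand
#'   matches either strand) or `"ignore"`.
#' @return A tibble of hosting pairs sorted by (gene start, mir start,
#'   mir id): columns `gene`, `mir`, `chrom`, `gene_start`, `gene_end`,
#'   `mir_start`, `mir_end`, `same_strand`.
#' @export
map_hosted_mirs <- function(genes, mirs, strand_policy = c("same", "ignore")) {
  strand_policy <- match.arg(strand_policy)
  empty <- tibble::tibble(
    gene = character(), mir = character(), chrom = character(),
    gene_start = integer(), gene_end = integer(),
    mir_start = integer(), mir_end = integer(), same_strand = logical()
  )
  if (nrow(genes) == 0 || nrow(mirs) == 0) return(empty)
  if (anyDuplicated(genes$feature_id)) {
    stop("duplicated gene feature_id(s): ",
         paste(unique(genes$feature_id[duplicated(genes$feature_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(mirs$feature_id)) {
    stop("duplicated miR feature_id(s): ",
         paste(unique(mirs$feature_id[duplicated(mirs$feature_id)]), collapse = ", "),
         call. = FALSE)
  }
  gr_g <- features_to_granges(genes)
  gr_m <- features_to_granges(mirs)
  hits <- GenomicRanges::findOverlaps(gr_m, gr_g, type = "within",
                                      ignore.strand = (strand_policy == "ignore"))
  if (length(hits) == 0) return(empty)
  gi <- S4Vectors::subjectHits(hits)
  mi <- S4Vectors::queryHits(hits)
  pairs <- tibble::tibble(
    gene = genes$feature_id[gi],
    mir = mirs$feature_id[mi],
    chrom = genes$chrom[gi],
    gene_start = genes$start[gi],
    gene_end = genes$end[gi],
    mir_start = mirs$start[mi],
    mir_end = mirs$end[mi],
    same_strand = genes$strand[gi] == mirs$strand[mi] &
      genes$strand[gi] %in% c("+", "-")
  )
  dplyr::arrange(pairs, .data$gene_start, .data$mir_start, .data$mir)
}

#' Filter candidate genes by tissue-specific escape evidence
#'
#' Escape from XCI is tissue-variable, so a gene called escaper from
#' hybrid-line or allelic data must also show escape in the tissue where
#' validation is performed. A gene is retained iff it has a record for the
#' tissue, is expressed there, and has a strictly positive sex-bias log fold
#' change (female-biased expression, the signature of escape). Every
#' excluded gene gets exactly one reason: `not_in_table`, `not_expressed`
#' or `nonpositive_logfc`.
#'
#' @param genes Character vector of approved symbols.
#' @param tissue_table Tibble from [read_tissue_table()].
#' @param tissue Tissue name, e.g. `"fibroblast"`.
#' @return A list with `retained` (symbols, input order) and `exclusions`
#'   (tibble `gene`, `reason`).
#' @export
filter_tissue_escape <- function(genes, tissue_table, tissue) {
  rows <- tissue_table[tissue_table$tissue == tissue, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("tissue '", tissue, "' absent from the tissue table", call. = FALSE)
  }
  genes <- unique(genes)
  idx <- match(genes, rows$gene)
  expressed <- rows$expressed[idx]
  logfc <- rows$logfc[idx]
  reason <- rep(NA_character_, length(genes))
  reason[is.na(idx)] <- "not_in_table"
  reason[!is.na(idx) & !expressed] <- "not_expressed"
  reason[!is.na(idx) & expressed & !(logfc > 0)] <- "nonpositive_logfc"
  list(
    retained = genes[is.na(reason)],
    exclusions = tibble::tibble(gene = genes[!is.na(reason)],
                                reason = reason[!is.na(reason)])
  )
}

#' @noRd
mir_family <- function(mir_ids) {
  m <- regmatches(tolower(mir_ids),
                  regexpr("(let-7|mir-[0-9]+)", tolower(mir_ids)))
  out <- rep(NA_character_, length(mir_ids))
  out[regexpr("(let-7|mir-[0-9]+)", tolower(mir_ids)) > 0] <- m
  out
}

#' Select negative-control miRNAs from XCI-subject loci
#'
#' Picks up to `k` miRNAs whose loci lie inside genes subject to XCI
#' (inactivated), to serve as negative controls expected to show no sex
#' bias. Selection prefers members of the same miR family as a candidate
#' miR (a family-matched control shares sequence context), then proceeds in
#' lexicographic ID order; hosted escaper miRs are excluded. Containment is
#' evaluated ignoring strand, since only the locus' silencing status
#' matters.
#'
#' @param mirs Feature tibble of all miR loci.
#' @param hosted_mir_ids miR IDs already hosted in escaper genes (excluded).
#' @param inactivated_genes Feature tibble of XCI-subject gene loci.
#' @param k Number of controls to select.
#' @param candidate_mirs miR IDs of the escaper candidates, used for the
#'   family preference.
#' @return Character vector of up to `k` miR IDs (empty, with a warning,
#'   when no eligible control exists and `k > 0`).
#' @export
select_control_mirs <- function(mirs, hosted_mir_ids, inactivated_genes,
                                k = 2L, candidate_mirs = character()) {
  if (k == 0L) return(character())
  pairs <- map_hosted_mirs(inactivated_genes, mirs, strand_policy = "ignore")
  pool <- setdiff(unique(pairs$mir), hosted_mir_ids)
  if (length(pool) == 0) {
    warning("no eligible negative-control miR in XCI-subject loci", call. = FALSE)
    return(character())
  }
  fams <- unique(mir_family(candidate_mirs))
  fams <- fams[!is.na(fams)]
  preferred <- pool[mir_family(pool) %in% fams]
  rest <- setdiff(pool, preferred)
  utils::head(c(sort(preferred), sort(rest)), k)
}
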