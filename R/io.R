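# Readers and writers for the pipeline's external table formats.
#
# Canonical tabular dialect: UTF-8 TSV with a header row. GFF3 and GMT follow
# their respective standards. Unparseable data rows are dropped with a
# warning; if more than half of the data rows fail, loading aborts (guard
# against a wrong or corrupt file). See docs/formats.md for column schemas.

MAX_BAD_ROW_FRACTION <- 0.5

#' @noRd
stop_if_missing_cols <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' @noRd
read_tsv_chr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = c("", "NA"))
}

#' @noRd
drop_bad_rows <- function(df, bad, path, why) {
  if (!any(bad)) return(df)
  if (mean(bad) > MAX_BAD_ROW_FRACTION) {
    stop("more than half of the rows in '", path, "' are invalid (", why,
         "); refusing to load", call. = FALSE)
  }
  # +1 for the header line
  warning("dropping ", sum(bad), " invalid row(s) in '", path, "' (", why,
          ") at line(s): ", paste(utils::head(which(bad) + 1L, 10L), collapse = ", "),
          call. = FALSE)
  df[!bad, , drop = FALSE]
}

#' Read an escape-call table
#'
#' Loads per-gene XCI escape evidence in one of two dialects. The `carrel`
#' dialect records in how many of the somatic-cell hybrid lines tested
#' (default 9) a gene is expressed from the inactive X; the `cotton` dialect
#' records the Xi/Xa allelic expression ratio. Classification into
#' escape/variable/inactivated is a separate step ([classify_escape_calls()]);
#' here `category` is always `"unknown"`.
#'
#' @param path Path to a headered TSV. Carrel dialect requires columns
#'   `gene_id`, `n_expressing` (optional `n_lines`, default 9); cotton dialect
#'   requires `gene_id`, `xi_xa_ratio`.
#' @param dialect `"carrel"` or `"cotton"`.
#' @return A tibble of escape calls with columns `gene_id`, `dataset`,
#'   `n_expressing`, `n_lines`, `xi_xa_ratio`, `category`, one row per input
#'   row, order preserved.
#' @export
read_escape_table <- function(path, dialect = c("carrel", "cotton")) {
  dialect <- match.arg(dialect)
  df <- read_tsv_chr(path)
  if (dialect == "carrel") {
    stop_if_missing_cols(df, c("gene_id", "n_expressing"), path)
    n_expressing <- suppressWarnings(as.integer(df$n_expressing))
    n_lines <- if ("n_lines" %in% names(df)) {
      suppressWarnings(as.integer(df$n_lines))
    } else {
      rep(9L, nrow(df))
    }
    n_lines[is.na(n_lines)] <- 9L
    bad <- is.na(df$gene_id) | is.na(n_expressing) |
      n_expressing < 0L | n_expressing > n_lines
    keep <- !bad
    df <- drop_bad_rows(df, bad, path, "non-numeric or out-of-range count")
    calls <- tibble::tibble(
      gene_id = df$gene_id,
      dataset = "carrel",
      n_expressing = n_expressing[keep],
      n_lines = n_lines[keep],
      xi_xa_ratio = NA_real_,
      category = "unknown"
    )
  } else {
    stop_if_missing_cols(df, c("gene_id", "xi_xa_ratio"), path)
    ratio <- suppressWarnings(as.numeric(df$xi_xa_ratio))
    bad <- is.na(df$gene_id) | is.na(ratio) | ratio < 0
    keep <- !bad
    df <- drop_bad_rows(df, bad, path, "non-numeric or negative Xi/Xa ratio")
    calls <- tibble::tibble(
      gene_id = df$gene_id,
      dataset = "cotton",
      n_expressing = NA_integer_,
      n_lines = NA_integer_,
      xi_xa_ratio = ratio[keep],
      category = "unknown"
    )
  }
  calls
}

GENE_TYPES <- c("gene", "protein_coding_gene", "pseudogene")
MIRNA_TYPES <- c("miRNA", "miRNA_primary_transcript", "pre_miRNA")

#' Read genomic features from GFF3
#'
#' Imports gene and/or miRNA loci from a GFF3 file (1-based inclusive
#' coordinates, kept as such internally -- the Bioconductor convention).
#' Records with `start > end`, a wrong column count, or no usable
#' `Name`/`ID` attribute are dropped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param kind_filter Optional; restrict to `"gene"` or `"mirna"` features.
#' @return A tibble with columns `feature_id`, `kind` (`gene`/`mirna`),
#'   `chrom`, `start`, `end` (1-based inclusive), `strand`
#'   (`+`, `-` or `unknown`).
#' @export
read_gff3 <- function(path, kind_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.null(kind_filter)) {
    kind_filter <- match.arg(kind_filter, c("gene", "mirna"))
  }
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^#", lines) & nzchar(trimws(lines))
  data_idx <- which(is_data)
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nfield_ok <- vapply(fields, length, integer(1)) == 9L
  coord_ok <- rep(FALSE, length(fields))
  coord_ok[nfield_ok] <- vapply(fields[nfield_ok], function(f) {
    s <- suppressWarnings(as.numeric(f[4]))
    e <- suppressWarnings(as.numeric(f[5]))
    !is.na(s) && !is.na(e) && s <= e
  }, logical(1))
  bad <- !(nfield_ok & coord_ok)
  if (any(bad)) {
    warning("rejecting ", sum(bad), " malformed GFF3 record(s) in '", path,
            "' at line(s): ", paste(utils::head(data_idx[bad], 10L), collapse = ", "),
            call. = FALSE)
  }
  keep_lines <- lines[setdiff(seq_along(lines), data_idx[bad])]
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(keep_lines, tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")

  type <- as.character(gr$type)
  kind <- rep(NA_character_, length(gr))
  kind[type %in% GENE_TYPES] <- "gene"
  kind[type %in% MIRNA_TYPES] <- "mirna"

  nm <- if ("Name" %in% names(S4Vectors::mcols(gr))) as.character(gr$Name) else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else rep(NA_character_, length(gr))
  feature_id <- ifelse(is.na(nm) | !nzchar(nm), id, nm)
  no_id <- is.na(feature_id) | !nzchar(feature_id)
  if (any(no_id & !is.na(kind))) {
    warning("rejecting ", sum(no_id & !is.na(kind)),
            " GFF3 record(s) without a Name or ID attribute in '", path, "'",
            call. = FALSE)
  }

  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "unknown"
  feats <- tibble::tibble(
    feature_id = feature_id,
    kind = kind,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand
  )
  feats <- feats[!is.na(feats$kind) & !no_id, , drop = FALSE]
  if (!is.null(kind_filter)) feats <- feats[feats$kind == kind_filter, , drop = FALSE]
  feats
}

#' Write genomic features to GFF3
#'
#' Inverse of [read_gff3()]: 1-based inclusive coordinates are written
#' unchanged, so a write/read round trip preserves them exactly.
#'
#' @param features Feature tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  strand <- features$strand
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = strand
  )
  gr$type <- ifelse(features$kind == "mirna", "miRNA", "gene")
  gr$ID <- features$feature_id
  gr$Name <- features$feature_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @noRd
features_to_granges <- function(features) {
  strand <- features$strand
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = strand
  )
  names(gr) <- features$feature_id
  gr
}

#' Read pathway gene sets from GMT
#'
#' Standard GMT: one set per line, `name <TAB> description <TAB> member...`.
#' Duplicate members within a set are collapsed; an empty set or a duplicated
#' set name is an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nms <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name(s) in '", path, "': ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    stop("empty gene set(s) in '", path, "': ",
         paste(names(sets)[empty], collapse = ", "), call. = FALSE)
  }
  sets
}

#' Write pathway gene sets to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' Headered TSV with columns `mir_id`, `gene` and optional `evidence`.
#' Repeated (miR, gene) pairs are collapsed to the first occurrence.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `mir_id`, `gene`, `evidence`, one row per
#'   unique interaction.
#' @export
read_targets <- function(path) {
  df <- read_tsv_chr(path)
  stop_if_missing_cols(df, c("mir_id", "gene"), path)
  if (!"evidence" %in% names(df)) df$evidence <- NA_character_
  bad <- is.na(df$mir_id) | is.na(df$gene)
  df <- drop_bad_rows(df, bad, path, "missing miR or gene identifier")
  out <- tibble::as_tibble(df[, c("mir_id", "gene", "evidence")])
  dplyr::distinct(out, .data$mir_id, .data$gene, .keep_all = TRUE)
}

#' Read a qPCR Ct table
#'
#' Headered TSV with columns `sample_id`, `group`, `assay`, `replicate`,
#' `ct`. Every Ct must be finite and positive; a duplicated
#' (sample, assay, replicate) triple is an error.
#'
#' @param path Path to the TSV.
#' @return A tibble of replicate-level Ct values.
#' @export
read_qpcr <- function(path) {
  df <- read_tsv_chr(path)
  stop_if_missing_cols(df, c("sample_id", "group", "assay", "replicate", "ct"), path)
  ct <- suppressWarnings(as.numeric(df$ct))
  replicate <- suppressWarnings(as.integer(df$replicate))
  bad <- is.na(df$sample_id) | is.na(df$group) | is.na(df$assay) |
    is.na(replicate) | is.na(ct) | !is.finite(ct) | ct <= 0
  keep <- !bad
  df <- drop_bad_rows(df, bad, path, "missing field or non-positive Ct")
  out <- tibble::tibble(
    sample_id = df$sample_id,
    group = df$group,
    assay = df$assay,
    replicate = replicate[keep],
    ct = ct[keep]
  )
  key <- paste(out$sample_id, out$assay, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), , drop = FALSE]
    stop("duplicate (sample, assay, replicate) row(s) in '", path, "', e.g. ",
         dup$sample_id[1], " / ", dup$assay[1], " / replicate ", dup$replicate[1],
         call. = FALSE)
  }
  out
}

#' Read an HGNC-style symbol map
#'
#' Headered TSV with columns `input_id`, `status`
#' (`approved`/`alias`/`previous`/`withdrawn`) and `approved_symbol`
#' (required unless status is `withdrawn`).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `input_id`, `status`, `approved_symbol`.
#' @export
read_symbol_map <- function(path) {
  df <- read_tsv_chr(path)
  stop_if_missing_cols(df, c("input_id", "status"), path)
  if (!"approved_symbol" %in% names(df)) df$approved_symbol <- NA_character_
  ok_status <- df$status %in% c("approved", "alias", "previous", "withdrawn")
  needs_sym <- df$status %in% c("approved", "alias", "previous")
  bad <- is.na(df$input_id) | !ok_status | (needs_sym & is.na(df$approved_symbol))
  df <- drop_bad_rows(df, bad, path, "unknown status or missing approved symbol")
  tibble::as_tibble(df[, c("input_id", "status", "approved_symbol")])
}

#' Read a tissue escape table
#'
#' Headered TSV with columns `gene`, `tissue`, `expressed` (TRUE/FALSE or
#' 1/0) and `logfc` (sex-bias log fold change; positive in females evidences
#' escape in that tissue).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene`, `tissue`, `expressed`, `logfc`.
#' @export
read_tissue_table <- function(path) {
  df <- read_tsv_chr(path)
  stop_if_missing_cols(df, c("gene", "tissue", "expressed", "logfc"), path)
  expressed <- toupper(df$expressed) %in% c("TRUE", "T", "1", "YES")
  logfc <- suppressWarnings(as.numeric(df$logfc))
  bad <- is.na(df$gene) | is.na(df$tissue) | (expressed & !is.finite(logfc))
  keep <- !bad
  df <- drop_bad_rows(df, bad, path, "missing gene/tissue or non-finite logFC")
  tibble::tibble(
    gene = df$gene,
    tissue = df$tissue,
    expressed = expressed[keep],
    logfc = logfc[keep]
  )
}

#' Write a stage report
#'
#' Serializes a result object to JSON (any list-like report) or TSV (data
#' frames only). Output is byte-stable for a fixed input.
#'
#' @param report A list or data frame.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(report)) {
      stop("TSV reports require a data frame", call. = FALSE)
    }
    readr::write_tsv(report, path, progress = FALSE)
  } else {
    report <- unclass_deep(report)
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", null = "null")
  }
  invisible(path)
}

#' @noRd
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}

#' Read back a JSON stage report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return The deserialized report as a list (data frames restored as data
#'   frames).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
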