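# XCI escape classification, symbol normalization and dataset reconciliation.

#' Classify hybrid-line escape calls
#'
#' Under the hybrid-line dialect a gene is an XCI escaper when it is
#' expressed from the inactive X in at least `escape_min` of the hybrid
#' lines tested, inactivated when expressed in at most `inactive_max`, and
#' subject to variable escape in between. Defaults encode the conventional
#' rule for a 9-line panel: >= 7/9 escape, 0-2 inactivated, 3-6 variable.
#'
#' @param calls Escape-call tibble from [read_escape_table()], carrel dialect.
#' @param escape_min Minimum number of expressing lines for `escape`.
#' @param inactive_max Maximum number of expressing lines for `inactivated`.
#' @return `calls` with `category` filled in.
#' @export
classify_carrel <- function(calls, escape_min = 7L, inactive_max = 2L) {
  if (any(calls$dataset != "carrel")) {
    stop("classify_carrel() requires carrel-dialect calls", call. = FALSE)
  }
  if (any(is.na(calls$n_expressing))) {
    stop("carrel calls must carry n_expressing", call. = FALSE)
  }
  if (!(inactive_max >= 0 && inactive_max < escape_min)) {
    stop("need 0 <= inactive_max < escape_min", call. = FALSE)
  }
  if (any(escape_min > calls$n_lines)) {
    stop("escape_min exceeds the number of lines tested", call. = FALSE)
  }
  calls$category <- ifelse(calls$n_expressing >= escape_min, "escape",
                           ifelse(calls$n_expressing <= inactive_max,
                                  "inactivated", "variable"))
  calls
}

#' Classify Xi/Xa-ratio escape calls
#'
#' Under the allelic-ratio dialect a gene escapes XCI when its inactive-X
#' expression is at least `escape_ratio_min` of its active-X expression
#' (boundary inclusive); otherwise it is inactivated. This dialect has no
#' variable tier.
#'
#' @param calls Escape-call tibble from [read_escape_table()], cotton dialect.
#' @param escape_ratio_min Minimum Xi/Xa ratio for `escape` (default 0.10,
#'   the conventional threshold in the XCI literature).
#' @return `calls` with `category` filled in.
#' @export
classify_cotton <- function(calls, escape_ratio_min = 0.10) {
  if (any(calls$dataset != "cotton")) {
    stop("classify_cotton() requires cotton-dialect calls", call. = FALSE)
  }
  if (any(is.na(calls$xi_xa_ratio))) {
    stop("cotton calls must carry xi_xa_ratio", call. = FALSE)
  }
  if (any(calls$xi_xa_ratio < 0)) {
    stop("Xi/Xa ratios must be non-negative", call. = FALSE)
  }
  if (escape_ratio_min <= 0) stop("escape_ratio_min must be > 0", call. = FALSE)
  calls$category <- ifelse(calls$xi_xa_ratio >= escape_ratio_min,
                           "escape", "inactivated")
  calls
}

#' Classify escape calls of either dialect
#'
#' Dispatches each row to [classify_carrel()] or [classify_cotton()]
#' according to its `dataset` field.
#'
#' @inheritParams classify_carrel
#' @inheritParams classify_cotton
#' @return `calls` with `category` filled in, original row order preserved.
#' @export
classify_escape_calls <- function(calls, escape_min = 7L, inactive_max = 2L,
                                  escape_ratio_min = 0.10) {
  unknown <- setdiff(unique(calls$dataset), c("carrel", "cotton"))
  if (length(unknown) > 0) {
    stop("unknown dataset dialect(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx_car <- calls$dataset == "carrel"
  if (any(idx_car)) {
    calls[idx_car, ] <- classify_carrel(calls[idx_car, ], escape_min, inactive_max)
  }
  if (any(!idx_car)) {
    calls[!idx_car, ] <- classify_cotton(calls[!idx_car, ], escape_ratio_min)
  }
  calls
}

#' Normalize raw gene identifiers against a symbol map
#'
#' Resolves raw identifiers the way the HGNC multi-symbol checker does:
#' approved symbols pass through, aliases and previous symbols resolve to
#' their approved symbol, withdrawn and unmatched identifiers are dropped.
#' Two raw identifiers resolving to the same approved symbol collapse to one
#' entry (visible in the mapping log).
#'
#' @param raw_ids Character vector of raw identifiers (duplicates allowed).
#' @param symbol_map Symbol map tibble from [read_symbol_map()].
#' @return A list with `symbols` (approved symbols, deduplicated,
#'   first-occurrence order) and `log` (one `SymbolMapping` row per input:
#'   `input_id`, `status`, `approved_symbol`).
#' @export
normalize_symbols <- function(raw_ids, symbol_map) {
  if (is.null(symbol_map) || nrow(symbol_map) == 0) {
    stop("symbol map is empty; cannot normalize identifiers", call. = FALSE)
  }
  idx <- match(raw_ids, symbol_map$input_id)
  status <- ifelse(is.na(idx), "unmatched", symbol_map$status[idx])
  approved <- ifelse(status %in% c("approved", "alias", "previous"),
                     symbol_map$approved_symbol[idx], NA_character_)
  log <- tibble::tibble(input_id = raw_ids, status = status,
                        approved_symbol = approved)
  symbols <- unique(approved[!is.na(approved)])
  list(symbols = symbols, log = log)
}

#' Reconcile two escaper gene sets
#'
#' Computes the intersection, union and set differences of two sets of
#' approved symbols, e.g. the escaper sets called from two independent XCI
#' studies. Satisfies inclusion-exclusion:
#' `|union| = |A| + |B| - |intersection|`.
#'
#' @param set_a,set_b Character vectors of approved symbols.
#' @param mapping_log Optional combined symbol-mapping log to attach.
#' @return An object of class `xci_reconcile`: a list with `set_a`, `set_b`,
#'   `intersection`, `union`, `only_a`, `only_b`, `sizes`, `mapping_log`.
#' @export
reconcile <- function(set_a, set_b, mapping_log = NULL) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  res <- list(
    set_a = set_a,
    set_b = set_b,
    intersection = intersect(set_a, set_b),
    union = union(set_a, set_b),
    only_a = setdiff(set_a, set_b),
    only_b = setdiff(set_b, set_a),
    mapping_log = mapping_log
  )
  res$sizes <- list(
    set_a = length(set_a), set_b = length(set_b),
    intersection = length(res$intersection), union = length(res$union),
    only_a = length(res$only_a), only_b = length(res$only_b)
  )
  structure(res, class = "xci_reconcile")
}

#' @export
print.xci_reconcile <- function(x, ...) {
  s <- x$sizes
  cat("XCI escaper reconciliation\n")
  cat(sprintf("  |A| = %d, |B| = %d\n", s$set_a, s$set_b))
  cat(sprintf("  intersection = %d, union = %d (only A = %d, only B = %d)\n",
              s$intersection, s$union, s$only_a, s$only_b))
  invisible(x)
}
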