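---
title: "Discovering X-linked miRNAs that escape X inactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering X-linked miRNAs that escape X inactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcimir)
```

## The biological question and the model behind the pipeline

In XX cells one X chromosome is epigenetically silenced so that X-linked
gene dosage matches XY cells. Silencing is incomplete: a minority of
X-linked genes — *XCI escapers* — are expressed from the inactive X (Xi) as
well as the active X (Xa), and are therefore expressed at higher levels in
XX than in XY cells. The X chromosome is also rich in miRNA loci, and many
miRNAs reside *inside* the body of a protein-coding gene, where they are
typically co-transcribed with their host. The pipeline composes these two
observations: a miRNA hosted in a gene that robustly escapes XCI is itself
a candidate for female-biased expression, and if its validated targets
over-represent a phenotype-relevant pathway (here, apoptosis), it is a
candidate regulator of a sex-dimorphic phenotype.

The stages are:

1. **Escape calling.** Two evidence dialects are supported. In the
   *hybrid-line* dialect a gene's evidence is the number of somatic-cell
   hybrid lines (out of `n_lines`, default 9) in which it is expressed from
   the Xi: at least `escape_min = 7` is an escaper, at most
   `inactive_max = 2` is inactivated, 3–6 is variable escape. In the
   *allelic-ratio* dialect the evidence is the Xi/Xa expression ratio, with
   escape at `ratio_min = 0.10` and above (see "Open choices" below).
2. **Symbol normalization and reconciliation.** Raw identifiers are
   resolved against an HGNC-style map (approved/alias/previous resolve,
   withdrawn and unmatched drop, collapses are logged), and the two
   escaper sets are reconciled into intersection and union. Only full
   escapers enter the sets: variable-escape genes are excluded, because
   tissue- and subject-variable escape is exactly what the later tissue
   filter must not take for granted.
3. **Host mapping.** A gene hosts a miRNA when the miR locus lies fully
   inside the gene interval on the same chromosome, boundaries inclusive —
   containment, not overlap, since a miR produced from a host's intron or
   UTR lies within the gene body. The candidate gene set is the escaper
   *union*: a gene escaping in either study deserves follow-up.
4. **Tissue filter.** Escape varies across tissues, so host genes must
   additionally show escape in the tissue used for validation: a record in
   the tissue table, `expressed = TRUE`, and a strictly positive sex-bias
   log fold change (female-biased expression being the expression-level
   signature of escape; a zero or negative logFC is evidence against
   escape in that tissue, so zero excludes).
5. **Targets and pathway enrichment.** Each retained precursor is expanded
   to the mature arm IDs present in the validated-interaction table, the
   target set is tested per pathway with the upper-tail hypergeometric
   test `P(X >= k)`, `X ~ Hyper(N, K, n)`, and p-values are
   Benjamini–Hochberg adjusted across the tested sets.
6. **Ranking.** Candidates are ordered by: tissue-supported escape;
   enrichment of the pathway of interest at `p_adjusted <= alpha = 0.05`;
   at least `min_targets = 10` validated targets; target count;
   lexicographic ID as the final deterministic tie-break. Every criterion
   is kept as an audit column.
7. **Validation arithmetic.** Group-versus-group relative quantification by
   2^−ΔΔCt: per-sample Ct is the replicate mean, the reference Ct is the
   arithmetic mean of the reference assays (equivalent to the geometric
   mean of reference quantities — the standard multi-reference
   convention), ΔCt = target − reference averaged per group,
   ΔΔCt = test − calibrator, fold = 2^−ΔΔCt. A fold change is significant
   when `max(fold, 1/fold) >= 1.5` — two-sided, since down-regulation is
   equally meaningful, and boundary-inclusive. `mfi_ratio()` supplies the
   exact Bax/Bcl-2 median-fluorescence quotient used as an
   apoptotic-proneness index.

Negative controls are selected from the opposite stratum: miRs whose loci
lie inside genes consistently *subject* to XCI (inactivated in every
dataset that calls them and in neither escaper set), preferring a member of
the same miR family as a candidate (a family-matched control shares
sequence context), then lexicographic order. Containment for control
selection ignores strand — only the silencing status of the locus matters.

## A worked run on the reference fixture

Every input is generated by the seeded synthetic-data module; the
`fixture_bundle()` writes a complete bundle whose planted relations encode
the known chrX escaper/miRNA biology (six host genes containing twelve miR
loci; CTPS2 and PUDP escaping in fibroblasts; miR-548am-5p with 332
validated targets of which eight are apoptosis genes).

```{r run}
dir <- file.path(tempdir(), "bundle")
fixture_bundle(dir)
report <- run_all(file.path(dir, "config.yaml"))
report
```

The report reproduces, from the generated files alone, escaper sets of 64
and 65 symbols sharing 23 (union 106), 12 hosting pairs across 6 genes,
retention of CTPS2 and PUDP by the fibroblast filter, selection of the
family-matched controls, rank 1 for miR-548am-5p, and recovery of the
planted 5-fold XX/XY difference with no fold change in the controls.

```{r enrich}
e <- report$enrichment$results
e[e$mir_id == "hsa-miR-548am-5p" & e$set_name == "APOPTOSIS", ]
```

## What the generator emulates — and what it does not

The generator reproduces the *relational* structure of the real datasets:
raw identifier lists larger than their normalized sets (alias duplicates,
withdrawn and unmatched identifiers, including the HDHD1 → PUDP renaming),
planted set sizes and overlap, the hosting topology with ≥ 50 intergenic
decoy miR loci, per-gene tissue records, exact target counts, and one
planted enrichment with every other set at its null expectation.
Coordinates live on a toy chromosome of a few Mb; only containment
topology is preserved, not real assembly coordinates, gene lengths, intron
structure or transcript isoforms. Expression magnitudes, Ct base levels
and noise are stylized (per-sample Normal(0, 0.4) baselines, per-replicate
Normal(0, σ) noise). Passing tests therefore demonstrate that the
*procedure* is correct and deterministic on inputs with the stated
structure — not that real escape-call, interaction or pathway databases
would yield these counts, which depend on database versions.

## Numerical and design choices

* **Coordinates.** External GFF3 is 1-based inclusive and is kept so
  internally (the GenomicRanges convention), making I/O conversion-free;
  containment semantics are unaffected by the convention.
* **Allelic-ratio threshold.** The 0.10 Xi/Xa cut-off is the conventional
  escape threshold in the XCI literature; it is inclusive at the boundary
  and exposed as `ratio_min` for sensitivity analysis, as are the
  hybrid-line boundaries.
* **Strand policy.** Intragenic miRs are usually co-oriented with their
  host, so `strand_policy = "same"` is the default (features of unknown
  strand match either); `"ignore"` is available and can only add pairs.
* **Enrichment background.** The union of all loaded pathway members, a
  declared and reproducible default (overridable), with the query
  intersected against it before testing. The hypergeometric statistic is
  the standard over-representation test and is verified exhaustively
  against a counting oracle for all configurations with N ≤ 25.
* **Null calibration.** The type-I-error simulation uses N = 40, K = 10,
  n = 10, where the largest attainable discrete tail probability at or
  below 0.05 is 0.0498 — essentially nominal — so the empirical rejection
  rate is interpretable against a 0.05 ± 0.02 band. With other
  configurations the discrete test is conservative and the band would
  test the wrong thing.
* **Group-level calibrator.** `delta_delta_ct()` reports the
  group-versus-group fold (the contrast the validation experiment plots);
  `per_sample = TRUE` additionally reports each sample's fold against the
  calibrator-group mean ΔCt. Whether per-sample folds should be taken
  against the sample's own group mean or the opposite group's is left to
  the caller — both are one flag away and neither is asserted as canonical.
* **Problem sizes.** Test simulations use 2,000 null replicates, 25 random
  annotations (≤ 200 features), 200 qPCR cohorts and 10 random
  escape-table specs — sizes at which every stochastic band is stable
  across seeds while the whole suite stays interactive.
* **Degenerate inputs.** Empty escape tables, empty candidate lists, empty
  gene sets and vacuous control pools all return empty results (with a
  warning where the outcome is surprising), never errors; a tissue absent
  from the whole table, a query outside the background, non-positive Ct or
  MFI values, and >50% unparseable rows are hard errors.

## Known limitations

Transcript-level structure is collapsed to gene-level intervals, so a
hosting call that depended on a specific isoform's boundaries would not be
distinguished. Containment is the only hosting criterion; a miR
overlapping a gene end is not called hosted. Amplification-efficiency
correction (Pfaffl-style) is out of scope for the ΔΔCt module, as is any
statistical testing of flow-cytometry distributions. The pipeline consumes
*validated* interaction tables only; it performs no target prediction, and
reproducing any specific live database's counts is explicitly not a goal.
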