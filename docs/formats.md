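# Input table formats

All tabular inputs are UTF-8, tab-separated, with a mandatory header row.
Unparseable data rows are dropped with a warning; loading aborts when more
than half of the rows fail (a guard against wrong-file mistakes). GFF3 and
GMT follow their standards.

## Escape calls — carrel dialect (`read_escape_table(..., "carrel")`)

| column | type | meaning |
|---|---|---|
| `gene_id` | string | raw gene identifier (pre-normalization) |
| `n_expressing` | integer | hybrid lines expressing the gene from the inactive X |
| `n_lines` | integer, optional | lines tested (default 9) |

## Escape calls — cotton dialect (`read_escape_table(..., "cotton")`)

| column | type | meaning |
|---|---|---|
| `gene_id` | string | raw gene identifier |
| `xi_xa_ratio` | number >= 0 | inactive-X expression as a fraction of active-X expression |

## Symbol map (`read_symbol_map`)

| column | type | meaning |
|---|---|---|
| `input_id` | string | raw identifier |
| `status` | `approved` / `alias` / `previous` / `withdrawn` | HGNC-style status |
| `approved_symbol` | string | required unless status is `withdrawn` |

## Genomic annotation (`read_gff3` / `write_gff3`)

Standard GFF3, 1-based inclusive coordinates. Genes are records of type
`gene` (also `protein_coding_gene`, `pseudogene`); miRNA loci are
`miRNA`, `miRNA_primary_transcript` or `pre_miRNA`. The feature identifier
is the `Name` attribute, falling back to `ID`. Strand `.` maps to
`unknown`.

## Tissue escape table (`read_tissue_table`)

| column | type | meaning |
|---|---|---|
| `gene` | string | approved symbol |
| `tissue` | string | tissue name |
| `expressed` | boolean | gene expressed in this tissue |
| `logfc` | number | sex-bias log fold change (positive in females evidences escape); must be finite when `expressed` |

## Target interactions (`read_targets`)

| column | type | meaning |
|---|---|---|
| `mir_id` | string | mature or precursor miR ID (arm suffixes are part of the ID) |
| `gene` | string | approved target symbol |
| `evidence` | string, optional | provenance tag |

Repeated (miR, gene) pairs collapse to the first occurrence.

## Pathway sets (`read_gmt` / `write_gmt`)

Standard GMT: `name <TAB> description <TAB> member1 <TAB> member2 ...`.

## qPCR Ct table (`read_qpcr`)

| column | type | meaning |
|---|---|---|
| `sample_id` | string | biological sample |
| `group` | string | contrast label, e.g. `XX` / `XY` |
| `assay` | string | TaqMan assay (target, reference or control miR) |
| `replicate` | integer | technical replicate index |
| `ct` | number > 0 | threshold cycle |

A duplicated (sample, assay, replicate) triple is an error.

## Reports (`write_report` / `read_report`)

JSON (any stage result; byte-stable for fixed input) or TSV (data frames).
`run_all()` writes `report.json`, `ranking.tsv` and the fully resolved
`config_resolved.yaml` to its output directory.

## Run configuration (`load_run_config`)

YAML with two maps: `paths` (keys `carrel`, `cotton`, `symbol_map`,
`genes_gff3`, `mirs_gff3`, `tissue_table`, `targets`, `pathways_gmt`,
optional `qpcr`; relative paths resolve against the YAML's directory) and
`params` (`escape_min`, `inactive_max`, `ratio_min`, `strand_policy`,
`tissue`, `pathway`, `alpha`, `min_targets`, `fold_threshold`,
`target_assay`, `reference_assays`, `group_test`, `group_calibrator`).
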