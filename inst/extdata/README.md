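Published per-category genotype-concordance counts (averaged replicate
tables for MDA-amplified YH cells and MALBAC-amplified SW480 cells against
their golden controls) and per-cell SNV detection counts for the three
deep-sequenced MDA-2 cells. `*_cells.tsv` hold the
(single-cell category, control category, share level, count) entries;
`*_totals.tsv` hold the per-category control and detected marginal totals
as printed (the MALBAC cell entries and its printed HOMref detected total
are mutually inconsistent in the source table, so the marginals are kept
authoritative). Used by the worked examples and the acceptance script.
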