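# airrbench

Benchmarking analytics for immunoglobulin heavy-chain (IGH) repertoire
annotation.

Antibody repertoire analysis starts by aligning each sequencing read to
germline V, D and J gene segments and annotating its CDR3 — the
hypervariable loop used to define clonotypes. Different annotation tools
ship different germline references, use different alignment algorithms, and
report CDR3s under different boundary conventions, so the same reads can
yield substantially different repertoires. `airrbench` implements the
analytical machinery needed to quantify those differences, together with a
synthetic-data module that emulates simulator-style repertoires and
annotator outputs with *known* ground truth, so every metric can be
exercised and validated end to end without live tool runs.

## What it computes

- **Germline reference comparison** — reference sets (IMGT GENE-DB-style
  FASTA) intersected at four naming levels: subgroup (`IGHV1`), gene
  (`IGHV1-18`), allele (`IGHV1-18*01`) and exact nucleotide sequence, as an
  UpSet-style region partition; plus tabulation of dated reference change
  logs (gene removals/additions, allele additions, sequence and metadata
  changes) and release-interval statistics.
- **Harmonization and preprocessing** — AIRR Rearrangement tables brought
  to a common schema: anchored CDR3s (`C...W` junctions) stripped to the
  core CDR3, synonymous gene names (identical sequence, different name)
  canonicalized, allele suffixes dropped at gene granularity; then an
  eight-rule exclusion filter (non-IgH, stop codon, out-of-frame,
  unproductive, orphon genes, CDR3 length ≤ 4 aa, singleton CDR3s,
  deduplication) with per-rule loss accounting.
- **Accuracy metrics** — against known originating germlines: cumulative
  mishit frequency *K/N* (mishits over records with a call, at gene level),
  per-subgroup frequencies *W/X*, and true-by-assigned confusion matrices.
- **CDR3 overlap** — multi-tool partitions of unique CDR3 amino-acid sets
  (raw, preprocessed, Top-N most frequent), with per-tool percentages
  (region count / tool total × 100), and discrepancy percentages over a
  fixed input size.
- **Similarity networks** — unique CDR3s as nodes, links at Levenshtein
  distance ≤ 1; average degree = 2·L/N classifies the repertoire (< 0.5
  diverse, > 0.5 polarized); shared-CDR3 sub-networks are compared by
  measuring their average degree in each parent network, and paired degree
  vectors by Pearson's *r* and Kendall's tau-b.
- **Processing speed** — sequences / (minutes × jobs).

## Worked example

Simulate a polarized repertoire (200 base clones, 1000 mutated descendants),
emulate an annotator with a 5% V-gene mishit rate and anchored CDR3 output,
then preprocess, score and network it:

```r
library(airrbench)

ref   <- generate_reference_set(n_v = 20, n_d = 8, n_j = 4,
                                n_synonyms = 1, seed = 1)
truth <- generate_repertoire(ref, polarized_config(n_base = 200, seed = 1))
tool  <- annotator_profile("toolX", mishit_rate_v = 0.05,
                           cdr3_convention = "anchored", seed = 2)
ann   <- emulate_annotator(truth, tool, ref)

syn <- build_synonym_map(ref, "gene")
h   <- harmonize(ann, "anchored", synonyms = syn, granularity = "gene")
res <- preprocess_filter(h)
res$report
#> <filter_report> 1200 -> 172 records (172 unique CDR3s)
#>      non_igh   stop_codon out_of_frame unproductive       orphon  cdr3_length
#>            0            0            0            0            0            0
#>    singleton        dedup
#>          343          685

mishit_frequency(h, truth, "V", synonyms = syn)
#> # A tibble: 1 × 4
#>   gene_type     K     N frequency
#>   <chr>     <int> <int>     <dbl>
#> 1 V            53  1200    0.0442

net <- build_network(res$records$cdr3_aa)
net
#> <cdr3_network> 172 nodes, 105 links, average degree 1.221
classify_diversity(net)
#> [1] "polarized"
```

Reading: of 1200 annotated reads, 343 CDR3s seen only once and 685
duplicates are removed, leaving 172 unique CDR3s. The injected 5% V error
is recovered as K/N = 53/1200 ≈ 0.044 (within binomial noise of 0.05). The
CDR3 network's average degree of 1.22 exceeds the 0.5 threshold, correctly
classifying the 1:5 base:mutated composition as polarized.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study on
synthetic data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R             # reference + diverse/polarized truths
Rscript analysis/02_germline.R             # reference comparison, change history
Rscript analysis/03_annotate_preprocess.R  # three emulated annotators, filtering
Rscript analysis/04_mishits.R              # V/D/J accuracy, subgroups, confusion
Rscript analysis/05_overlap.R              # CDR3 overlap partitions, Top 100
Rscript analysis/06_network.R              # networks, sub-networks, correlations
```

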