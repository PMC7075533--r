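---
title: "Benchmarking repertoire annotation: models, parameters and limitations"
author: "airrbench"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`airrbench` quantifies how immunoglobulin heavy-chain (IGH) annotation
outputs differ — across germline references, preprocessing, gene
assignment accuracy, CDR3 content and CDR3 similarity structure. This
vignette is the package's own account of the models it implements, the
parameters that matter, and what its synthetic data can and cannot show.

## The synthetic repertoire model

Real benchmark studies feed simulator-generated reads with known
originating germlines into live annotation tools. This package instead
*emulates* both sides, so every downstream metric has recoverable truth:

**Germline references** (`generate_reference_set()`). V, D and J genes are
random stop-free coding sequences with IMGT-style names
(subgroup `IGHV1` > gene `IGHV1-18` > allele `IGHV1-18*01`), 1–3 alleles
per gene (non-`*01` alleles differ by 1–2 substitutions). Two conventions
make junction extraction exact: V genes end in a conserved cysteine codon
(`TGT`) and J genes begin with a conserved tryptophan codon (`TGG`).
`n_synonyms` pairs of distinct V gene names carry byte-identical allele
sequences, reproducing the duplicate-name/identical-sequence situation in
real references that causes false mishits unless renamed. Default gene
counts in the analysis scripts (30 V / 10 D / 5 J) are a desk-scale
stand-in for the human locus (~50–100 functional V genes).

**Repertoires** (`generate_repertoire()`). A base sequence is a random
V–(N)D(N)–J recombinant: the CDR3 is 2–5 random residues, the translated D
gene (4–7 codons), and 2–5 more residues; its nucleotide form embeds the
true D sequence with back-translated flanks, giving core CDR3s of 8–17 aa
(junction `C` + CDR3 + `W`), in the range typical of human IGH. Mutated
sequences descend from bases through lineage trees: each mutant copies a
uniformly chosen earlier member of its clone and applies
`max(1, Poisson(mutation_rate))` nucleotide substitutions. The default
`mutation_rate = 5` substitutions per event on a ~350 nt read (~1.5%)
matches the substitution-dominated character of somatic hypermutation.
Substitutions never touch the junction anchor codons and never introduce
in-frame stops (rejected and redrawn), so all simulated reads are
productive; unproductive records arise only from the annotator emulator's
flip rate or from hand-built test fixtures.

Two composition presets set the study conditions at configurable scale:

* **diverse** — base:mutated ratio 1:2, mutants spread uniformly over
  bases: many small clonal clusters (mean cluster size 3).
* **polarized** — ratio 1:5, mutants allocated by a power law over bases
  with exponent 1.5: a few large clonal expansions. The exponent is a
  design choice — the composition is described only qualitatively as
  highly repetitive, and 1.5 produces dominant clusters holding tens of
  percent of all mutants, as clonal expansions do.

Lineage structure is what makes the network analysis meaningful: a CDR3
variant that arises in a clone is inherited by that clone's descendants,
so in large (polarized) clusters variants recur, survive the singleton
filter, and sit at edit distance 1 from their neighbours.

**Annotator emulation** (`annotator_profile()`, `emulate_annotator()`).
Each emulated tool perturbs the truth with: per-gene-type mishit rates
(uniform redraw among the other genes of the type), targeted confusion
pairs (a specific wrong gene at a specific probability, emulating
systematic confusions between near-identical genes), naming granularity
(gene vs allele), CDR3 boundary convention (anchored junction vs core
CDR3), a drop rate (reads with no annotation), and a productive-flag flip
rate. All generators are pure functions of their arguments including the
seed.

One simulator idiosyncrasy is deliberately not emulated: real simulators
may emit slightly more or fewer sequences than requested; here counts are
exact (`n_base + n_mutated` records, always).

## Germline comparison

`intersect_references()` compares sets as exact strings at four levels —
subgroup, gene, allele, nucleotide sequence — and partitions the union
into exclusive regions (one per non-empty subset of sets, as in an UpSet
plot). The shared-by-all percentage is `|all-sets region| / |union|`,
rounded to integer percent; the union denominator is the only reading
consistent with published set totals of this analysis type. Gene-level
comparison is the common denominator when a compared set lacks allele
designations.

Change logs record five event types (gene removal, gene addition, allele
addition, sequence change, metadata change). `update_interval_stats()`
reports release gaps in fractional weeks (days/7) and uses the
nearest-rank percentile (no interpolation), which is reproducible across
numeric environments.

## Harmonization and preprocessing

`harmonize()` makes tool outputs comparable: anchored CDR3s are stripped
of the leading C and trailing W (records lacking the anchors are flagged
and left unchanged, never silently truncated), calls are canonicalized
through the synonym map (identical-sequence names map to the
lexicographically smallest), and allele suffixes are dropped at gene
granularity. The output is marked core, so harmonization is idempotent.

`preprocess_filter()` applies eight exclusion rules in a fixed order:
non-IgH, stop codon, out-of-frame, unproductive, orphon primary call,
CDR3 absent or ≤ 4 aa, singleton CDR3s, deduplication. The rule *set* is
the benchmark's; the *order* is a package choice, and only the per-rule
attribution depends on it (each record counts against the first rule that
rejects it) — the surviving records never do. Two choices make the filter
well-behaved:

* singletons are counted on the harmonized CDR3 weighted by
  `duplicate_count`, and deduplication aggregates `duplicate_count`, so
  filtering an already-filtered table removes nothing (idempotence) and
  Top-N frequencies survive deduplication;
* an absent CDR3 is treated as length 0 and removed by the length rule.

Singleton counting is within one tool's table; whether duplicates should
count across tools is left open in the source analysis, and within-table
counting keeps tools independent.

## Accuracy metrics

A *hit* assigns a read to its known originating germline gene; a *mishit*
to any other gene. The primary call is the first listed assignment.
Comparison is at gene level after synonym renaming (tools that do not
report alleles force this level). The cumulative frequency is K/N where N
counts only records *with* a call of that type — no-calls are alignment
failures, reported separately, not mishits. Per-subgroup rows (W/X) are
keyed by the *true* gene's subgroup, so they partition K and N and answer
where errors originate; reads without a call are likewise excluded from X.
Confusion matrices are row-conditional distributions of assigned given
true gene, with a "no call" column so rows sum to 1.

## CDR3 overlap

`cdr3_overlap()` partitions unique CDR3 sets into exclusive regions and
reports per-tool percentages: region count divided by *that tool's* total
unique count × 100 (so each tool's percentages sum to 100; reported to one
decimal, tested at two). `top_n_cdr3()` ranks by duplicate-weighted
frequency with lexicographic tie-breaking — the tie rule is a determinism
choice, not a claim about the source analysis, which is silent on ties.
`discrepancy_percentages()` expresses discrepant-read counts over a fixed
input size as rounded percentages.

## CDR3 similarity networks

Unique CDR3s are nodes; links join pairs at Levenshtein distance ≤ 1
(identical strings are one node, so self-links cannot occur). The
implementation enumerates candidate pairs by masked-position hashing
within length buckets: same-length pairs at distance 1 differ at exactly
one position, and length-difference-1 pairs at distance 1 differ by one
deletion, so hashing each string minus one position finds exactly the
distance-≤1 pairs. This is an optimization only — tests require
link-for-link identity with an all-pairs `utils::adist` oracle.

Average degree 2·L/N classifies the repertoire: < 0.5 diverse, > 0.5
polarized, exactly 0.5 reported as "boundary". Sub-networks of CDR3s
shared between tools are compared by measuring the subset's mean degree
*in each parent network* — links to nodes outside the subset count,
because degree differences between parents are precisely the signal. The
induced-subgraph alternative (degrees within the subset only) is exposed
behind `induced = TRUE` without any claim that it reproduces the published
analysis; worked examples in the source can be read either way, and the
parent-network reading is the one consistent with its full-matrix figure.
With three or more tools, a pair's shared CDR3s need not exist in a third
tool's network; `subnetwork_degree_matrix()` therefore measures each
subset only in its member networks (`NA` elsewhere), while
`shared_subnetwork_degrees()` stays strict and errors on missing nodes.

Degree correlations use Pearson's r and Kendall's tau-b (tie-corrected —
degree vectors are heavily tied; the variant is a package choice).
Constant vectors yield an undefined result with a reason rather than NaN.

Note that *emulated* tools share the truth's CDR3 strings by construction
(only gene calls, conventions and dropped reads differ), so their degree
correlations come out near 1 in the analysis scripts. The near-zero
correlations reported for real tools reflect algorithmic annotation
differences this emulation deliberately does not model.

## Numerical and degenerate-input conventions

* Every generator takes an explicit integer seed; identical arguments give
  byte-identical serialized output.
* Percentages: shared-germline as integer percent; overlap and losses to
  one decimal; discrepancy to two.
* Empty inputs: an empty FASTA reads as an empty set with a warning; an
  empty rearrangement table filters to an empty table with an all-zero
  report; an empty network has average degree 0 but cannot be classified.
* Errors name the offending record (malformed FASTA header, unknown true
  gene, missing sub-network node).

## Problem sizes

The shipped analyses and tests run at desk scale: diverse repertoires of
1000 base / 2000 mutated sequences and polarized of 200 base / 1000
mutated (the presets' 1:2 and 1:5 ratios at reduced size), references of
30/10/5 genes, five replicate seeds for the regime-separation checks, and
≤ 200-node networks for oracle comparisons. These sizes keep full runs in
seconds-to-minutes while leaving hundreds of unique CDR3s after
preprocessing.

## Limitations

The synthetic data validates the *analytics*, not real tools: it contains
no sequencing error model (no platform-specific artifacts such as
homopolymer errors), no indel hypermutation, no real germline sequences,
and no real annotation algorithms. Passing tests therefore demonstrate
that the metrics recover known injected structure — error rates within
binomial noise, composition regimes on the correct side of the 0.5
threshold, exact set arithmetic — not that any particular tool is
accurate. Allele-level accuracy benchmarking is likewise out of scope:
comparison is at gene level throughout.
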