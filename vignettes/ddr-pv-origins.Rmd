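---
title: "Tracing the origin of DNA-damage-repair pathogenic variants with paleoPV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the origin of DNA-damage-repair pathogenic variants with paleoPV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoPV)
```

## The question and the approach

Pathogenic variants (PVs) in DNA damage repair (DDR) genes — *BRCA1*,
*BRCA2*, the mismatch-repair genes, and their pathway neighbours —
predispose carriers to cancer. Where did they come from? Three sources are
conceivable: inheritance from non-human ancestors through cross-species
conservation, ancient standing variation in early modern humans, or recent
mutation within historical human populations. `paleoPV` implements the
analysis chain that discriminates among these: it projects a curated PV
catalog onto other vertebrate species, traces the same catalog in ancient
human genomes with an ancient-DNA-aware presence caller, partitions
ancient PVs by their sharing with modern African and non-African cohorts,
equalizes cohort sizes by rarefaction, compares per-gene PV counts across
selection regimes by bootstrap, and summarizes haplotype-dated founder-PV
ages.

Real cohort-scale inputs (thousands of ancient genomes, hundreds of
thousands of modern exomes) are not shipped. Instead a seeded synthetic
generator (`sim_config()`, `simulate_run()`) produces every input the
pipeline consumes with the statistical structure those data exhibit, so
the full chain runs self-contained and every statistical claim in the test
suite is checked against planted truth.

## Presence calling from ancient reads

Ancient DNA is fragmented, deduplication-hostile and chemically damaged:
post-mortem cytosine deamination reads out as C→T on forward-strand reads
and G→A on reverse-strand reads, concentrated at fragment ends. Rather
than de-novo genotyping, `call_presence()` asks a narrower question — is
the *known* alternate allele of a catalogued PV credibly observed in this
individual? — which is far better posed at sub-1× coverage.

The caller applies the standard aDNA quality steps in
`filter_observations()`: terminal-base exclusion, base/mapping-quality
thresholds, and duplicate collapse on the (fragment start, fragment end,
strand) key, keeping the best base quality. Defaults
(`caller_config()`):

| parameter | default | rationale |
|---|---|---|
| `terminal_trim` | 2 bases | deamination decays steeply with distance from the read end; trimming 2 removes the bulk while keeping short-fragment coverage |
| `min_base_qual` | 20 | conventional Phred floor |
| `min_map_qual` | 30 | excludes multi-mappers |
| `min_alt_reads` | 1 | low-coverage ancient genomes force permissive support |
| `min_alt_reads_damage` | 2 | stricter floor when *all* alternate support is deamination-consistent on its strand |
| `min_depth` | 1 | minimum surviving depth to declare absence |
| `min_zyg_reads` | 2 | per-allele support to assign zygosity |

Deamination handling is deliberately rule-based rather than likelihood
based: an alternate-supporting read is *damage-consistent* iff (ref = C,
alt = T, forward strand) or (ref = G, alt = A, reverse strand). Because
deamination is strand-specific, alternate support observed on both strands
can never be pure damage, so double-stranded support always counts as real
evidence regardless of the stricter threshold. Indel PVs carry their full
allele string in the pileup `base` column; the damage logic applies only
to single-nucleotide variants. Full probabilistic damage models and
contamination estimation are out of scope.

Raising any threshold can only shrink the surviving read set, so a site
called `absent` can never flip to `present` under a stricter
configuration; the suite checks this monotonicity on random pileups.

## Cohort sharing

`venn_partition()` splits the ancient PV set by membership in the modern
African and non-African PV sets. Two percentage bases are reported:
over the ancient PVs found in at least one modern cohort (the default
headline numbers) and over all ancient PVs. The shared-only base is the
package's reporting choice: the three shared classes then sum to 100%,
and ancient PVs seen in neither modern cohort — absence of evidence in
the modern catalogs, not evidence of loss — are listed separately rather
than diluting the comparison. Percentages round half-up
(`sharing_percentage()`), matching how such figures are conventionally
printed.

`load_comparison()` normalizes each cohort's per-gene count by that
cohort's nonredundant total before differencing, so a 10× difference in
cohort size does not masquerade as a load difference. Pathway counting
(`count_by_gene_and_pathway()`) is once-per-pathway: DDR pathway
membership is many-to-many, so pathway totals legitimately exceed the
nonredundant PV total.

`temporal_profile()` bins dated carriers into half-open `[start, end)`
intervals descending in years BP (default width 1,000 years — coarse
enough for radiocarbon dating uncertainty, fine enough to resolve the
5,000–1,000 BP enrichment the generator plants). Undated carriers are
excluded from bins and counted separately. Both carrier-occurrence
(default) and per-individual counting are available, because both margins
— PVs and people — are scientifically meaningful.

## Rarefaction

Raw sharing comparisons between cohorts of very different sizes are
confounded by discovery: a larger cohort discovers more PVs. `rarefy()`
equalizes sizes by drawing `n` individuals without replacement, taking
the union of their carried PVs, and recording the proportion of that
*discovered* set present in ancient humans — the denominator is the
subsample's own discovery, not the full cohort catalog (the alternative
denominator is a one-line change on the result matrices). Replicates that
discover nothing are flagged and excluded from summaries. The default
design interpolates 15 subgroup sizes on a log scale and uses 1,000
replicates per size, mirroring the design used at real cohort scale; the
per-(size, replicate) random streams are pre-derived from the root seed,
so results are bitwise reproducible and independent of execution order.

One synthetic-scale caveat the package's own tests respect: with a small
catalog, discovery saturates — at large subsample sizes both cohorts
discover essentially every PV and their sharing proportions converge to
the catalog's ancient fraction. The separation tests therefore use a
catalog (2,000 PVs) much larger than any subsample's discovery, which is
the regime the real data occupy.

## Cross-species projection

`project_and_match()` scores a human PV as shared with a species iff the
species' allele at the orthologous position equals the human alternate
allele; nucleotide-level identity is the default matching mode (the
choice between nucleotide- and protein-level matching is genuinely open;
the table layout carries whatever allele alphabet the upstream orthology
extraction produced, so protein residues work unchanged). Missing
orthology scores "not shared" but is tracked separately from
presence-of-reference. The nearest shared clade of a PV is the
minimum-rank (closest to human) clade among its sharing species, with the
default ranking Primate < Euarchontoglires < Laurasiatheria < Afrotheria
< Mammalia < Aves < Sarcopterygii < Fish, overridable via the
`clade_ranks` argument.

## Selection-class bootstrap

`bootstrap_group_test()` compares per-gene PV counts between selection
classes. Counts are transformed `log2(count + 1)` — the +1 admits
zero-PV genes and is switchable — genes are resampled with replacement
within each class, and the two-sided p-value is
`2·min(Pr(diff ≤ 0), Pr(diff ≥ 0))` over the bootstrap distribution with
a `+1/(n_boot+1)` correction so p is never exactly 0. Resampling genes
(not PVs) treats the gene as the exchangeable unit, which matches the
question "do genes under positive selection carry more PVs?". Under a
simulated null the p-values are approximately uniform
(Kolmogorov–Smirnov D ≈ 0.04 at 500 datasets × 2,000 resamples in the
suite).

## Founder ages

Founder-PV ages arrive as text in four shapes — points (`8,675`), ranges
(`1,500-750`, older bound first), lower bounds (`>250`) and upper bounds
(`<200`) — normalized for thousands separators and en-dashes by
`parse_age()`. For ordering and thresholding, the representative age is
the conservative "no younger than stated" reading: a range's older bound,
the stated value for either one-sided bound; midpoints are available for
summary statistics. The package ships a compiled literature table of 50
haplotype-dated DDR founder PVs (`read_founder_table()`), whose oldest
entry is *MUTYH* c.1103G>A at 8,675 years BP and in which only the two
*MUTYH* variants exceed 4,000 years BP.

## The synthetic generator

`sim_config()` fixes the study conditions; everything downstream of a
seed is deterministic. What it emulates, and the defaults:

- **Sparse, heterozygous carriage.** Carried-PV counts are
  zero-truncated Poisson (means 1.5 ancient, 1.2 modern); carriers are
  heterozygous with probability 0.98.
- **Differential ancient sharing.** Each carried PV of a modern
  individual is drawn from the ancient-present pool with the cohort's
  propensity: 0.5 for non-Africans, 0.17 for Africans. 40% of
  catalogued PVs are flagged ancient-present.
- **Dates.** Dated ancient individuals are uniform on 1,000–5,000 BP
  with a 5% tail reaching 40,000 BP; 110/1,266 ≈ 8.7% are undated.
- **Reads.** Depth is Poisson (mean 8, floor configurable); deamination
  flips a true C on a forward read to T with probability
  `0.2·exp(−0.3·d)` at distance `d` from the matching read end (the
  0.3-per-base decay makes the artifact negligible beyond ~10 bases),
  mirrored for G→A on reverse reads; 10% of reads are duplicated with
  the same fragment key; base and mapping qualities include a 5%
  low-quality tail each, plus a 0.1% generic error rate.
- **Cross-species structure.** Per-species sharing probabilities decay
  from Fish (0.006) to Primate (0.0003); with 99 species this leaves
  roughly 75–80% of PVs absent in all species, concentrating sharing in
  the distal clades. 15% of (PV, species) positions lack orthology.
- **Selection classes.** Per-gene counts are Poisson with class means
  30/10/4 (positive/neutral/negative).

What it does **not** emulate: linkage and haplotype structure, population
stratification within cohorts, contamination, reference bias, indel-rich
loci, or realistic gene length/mutability differences. Passing tests
therefore demonstrate the *machinery* — calling, counting, resampling and
their statistical calibration — not robustness to those real-data
complications.

## Numerical choices and problem sizes

Ties in duplicate collapse keep the first-seen read; catalogs preserve
file order; empty discovery and empty modern overlap are flagged rather
than silently zero; all percentages round half-up at the stated digit.
The test suite runs the chain at desk scale — e.g. genotype recovery on
~600 planted sites at depth ≥ 5 and deamination rate 0.2 (≥ 95%
recovered), rarefaction separation on 600-person cohorts over subgroup
sizes 25–400 with 150 replicates, bootstrap calibration at 500 × 2,000 —
sizes chosen so the whole suite completes in well under a minute of
compute per module while keeping Monte-Carlo noise far below the margins
being asserted.

## Limitations

The caller's thresholds are heuristics, not a calibrated genotype
likelihood; cohort labels are taken at face value (no ancestry
inference); the Venn and rarefaction analyses treat PV catalogs as sets,
ignoring allele frequency; and the founder and selection tables are
inputs — the package neither dates variants by haplotype decay nor
computes dN/dS.
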