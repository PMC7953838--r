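---
title: "parthenoscan: models, defaults, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{parthenoscan: models, defaults, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`parthenoscan` quantifies four genome features in parthenogenetic animals —
intragenomic heterozygosity, TE load, palindromic gene arrangements, and
HGT candidates — with one methodology per feature, and validates every stage
against synthetic genomes with exact truth. This vignette is the package's
account of the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## The k-mer mixture model

Reads are decomposed into canonical k-mers (lexicographic minimum of a
k-mer and its reverse complement under A<C<G<T) and binned by integer
coverage. The model treats the haploid genome as `G` k-length windows. With
per-site heterozygosity `r` in a divergence layer, a window overlaps at
least one variant site with probability `a = 1-(1-r)^k`. Each topology maps
window states to coverage peaks at exact multiples of the per-copy coverage
`lambda`:

* **AB** — heterozygous windows contribute two distinct k-mers at `lambda`,
  homozygous windows one k-mer at `2*lambda`: weights `{1: 2a, 2: 1-a}`.
* **AAB** — the two A copies are near-identical, B carries the divergence:
  `{1: a, 2: a, 3: 1-a}`. An allelic variant on one A copy produces the
  same `(lambda, 2*lambda)` signature as a homoeolog variant on B, so the
  two layers are inherently inseparable from the spectrum: the fit reports
  a single rate flagged *composite* (the sum of the two layers).
* **AAAB** — `{1: a, 3: a, 4: 1-a}`; **AABB** — `{2: 2a, 4: 1-a}`.
* **ABC** — two site classes: `one_hap` (exactly one copy carries a derived
  allele) and `triallelic` (all three copies distinct). Here the small-rate
  linear weights are not good enough: a window holding one-haplotype
  variants of two *different* copies has all three copies distinct and is
  indistinguishable from a triallelic window. The package therefore uses
  the exact window-occupancy algebra: with `s = r2 + r3`,
  `q0 = (1-s)^k` windows leave all copies identical,
  `b = 3[(1-s+r2/3)^k - q0]` leave exactly one copy distinct, and the rest
  make all three distinct, giving weights `{1: b+3t, 2: b, 3: q0}` with
  `t = 1-q0-b`. This reduces to the linear form at small rates and removes
  an ~10% downward bias in the composite rate at `r = 2%` and above.
  The tetraploid ABCD topology (simulation-only; not a fitting target)
  keeps the linear form.

Peak `i` is a negative binomial with mean `i*lambda` and size
`i*lambda/rho`, so the variance is `mu*(1+rho)` and peaks are evenly spaced
exactly. `rho` is bounded below at `1e-3` rather than 1: uniformly drawn
reads give Poisson-like k-mer counts (`rho -> 0`), and a hard `rho >= 1`
bound would misfit exactly the data the validation uses.

### Fitting: loss, initialization, ranges, ties

The loss is least squares on square-root counts (variance stabilization for
Poisson-like bin counts). For fixed shape parameters the amplitude has the
closed form `sqrt(G) = sum(sqrt(y*f)) / sum(f)`, so `G` is profiled out and
the optimizer (Nelder-Mead, two polishing rounds) works on
`log lambda, log rho`, and logit-transformed per-site rates bounded at 35%.
Multi-start runs from `lambda0 = argmax/i` for `i = 1..ploidy` crossed with
low and moderate rate starts; ties are broken by lowest residual, then
lowest heterozygosity. The fit range starts at the error cutoff — the first
local minimum of the histogram between coverage 1 and the first mode
(cutoff 1 when the histogram rises immediately, i.e. error-free reads) —
and initially extends to `1.4*ploidy*argmax`, wide enough when the haploid
peak is the mode (high-heterozygosity genomes). A second pass refits up to
`ploidy*lambda + 5` NB standard deviations, so the range neither truncates
the ploidy peak nor drags in unmodelled repeat bins; without this second
pass the AAAB fit at `r = 5%` loses its `4*lambda` peak and biases both `r`
and `G`. Mass above the modelled peaks is reported as a repeat fraction
(repeats are deliberately not modelled with duplication terms; the TE stage
quantifies them from reads), and a fraction above 30% raises a
range-exceeded warning — the regime where homoeolog divergence escapes
k-mer quantification (the bdelloid situation), which this package does not
attempt to resolve. Ploidy and topology are user-supplied;
`compare_topologies()` reports a residual ranking without committing.

## Heterozygous k-mer families and polyploid structure

With the count table retained, k-mers with coverage between the error
cutoff and `ploidy*lambda + 4*sqrt(ploidy*lambda*(1+rho))` are grouped into
families: connected components of the "differ at exactly one aligned
position, same flanks, either orientation" relation (implemented via
position-deleted canonical keys; components larger than 6 members are
discarded as repeat-induced). Two-member families are assigned the nearest
coverage template among AB `(lambda, lambda)`, AAB `(lambda, 2*lambda)`,
AABB `(2*lambda, 2*lambda)`, AAAB `(lambda, 3*lambda)` by minimum summed
relative deviation, with any member deviating more than 35% making the
family AMBIGUOUS; families of three or more members are multiallelic.
Fractions are reported relative to classified (non-AMBIGUOUS) families.
For the ABC validation condition we simulate `one_hap = 1%` and
`triallelic = 2%`: genomes of three mutually diverged copies are dominated
by loci where all copies differ, which is what makes the multiallelic
fraction the majority signal, while AAB genomes at 2% homoeolog divergence
put ≥85% of families in the single-copy-divergent class.

## TE load

Reads are subsampled without replacement to 0.5× of the haploid genome
size (fitted `G` or a user override) and assembled by greedy exact
suffix-prefix overlap (`min_overlap = 31`), longest overlaps first,
strand-aware (both orientations assembled, reverse-complement contigs
deduplicated, each read attributed to at most one contig). Contigs with
`min_reads >= 2` support are repeat candidates. One point deserves
honesty: at 0.5× coverage with 100 bp reads the expected number of exact
genomic overlaps per read is `2*(L-31)*c/L ≈ 0.7`, so roughly half the
reads of even a repeat-free genome pair up by chance. This does not harm
the estimator, because chance contigs have no library homology and
"unknown" repeat mass is excluded from the TE load by definition; the
repeat-free control therefore asserts a near-zero *load*, not a near-zero
assembly rate. Contigs and unassembled reads are annotated by seeded local
alignment (shared canonical 15-mer, then Smith-Waterman, match 2 /
mismatch -3, gap 5/2) against the library; hits need ≥70% identity over
≥80 bp, thresholds from common repeat-annotation practice. Annotated
nucleotides are the aligned query length times the read support the query
represents (for contigs, sampled read nucleotides per contig base), summed
per class over DNA, LINE, SINE, LTR and Helitron (RC/Helitron maps to
Helitron); anything else — unannotated repeat contigs, malformed labels,
non-TE repeat classes — goes to `unknown_repeat_nt` and never into the
load. Reads straddling a TE boundary with fewer than 80 aligned bases are
dropped, a ≲1 percentage-point downward bias at a 20% load; the 5-seed
validation at implanted loads of 5/10/20% recovers means within ±2
percentage points with a seed-to-seed SD below 1.5.

## Palindromes

All-vs-all protein homology uses seeded Smith-Waterman with BLOSUM62 (gap
11/1) and keeps hits with a Karlin-Altschul e-value ≤ 1e-5, identity ≥50%
and aligned length ≥100 residues (defaults in line with collinearity-tool
practice; the empirical null on random 300-aa proteins yields no hits).
Anchors are chained per scaffold pair by dynamic programming — rank gaps at
most 25 on both sides, subject ranks increasing (`same`) or decreasing
(`reverse`), score = anchors − 0.1 per skipped rank — with best-scoring
gene-disjoint chains extracted first and leftover anchors kept as
singleton blocks oriented by their strands. The chaining is verified
against exhaustive enumeration on small instances. Palindromes are blocks
passing all four hairpin requirements (same scaffold, reverse orientation,
opposite strands on every pair, non-overlapping sides); each rejection is
logged with its reason. Same-scaffold anchors within one rank are excluded
up front: immediately adjacent inverted copies are indistinguishable from
tail-to-tail tandem artifacts. Affected genes are counted once each.

Defaults count individual genes in palindromic arrangement
(`min_pairs = 1`); `mcscanx_strict = TRUE` requires blocks of ≥5 anchor
pairs, the strict synteny-block convention. The gene-order permutation
null (gene identities reshuffled over the annotated positions) is reported
alongside results as a guard against assembly-artifact positives; note
that under `min_pairs = 1` a shuffled genome retains singleton inverted
homolog pairs by chance, so the "zero palindromes under shuffling"
property is a statement about synteny blocks and is validated in strict
mode. Two structural choices in the generator keep implanted truth
well-defined: each palindrome's arms flank a spacer gene (as real
palindromes do), so the innermost anchor pair clears the tandem exclusion;
and distinct implants default to distinct scaffolds, because two
palindromes nested on one scaffold genuinely chain into a single merged
block under the gap rule — a property of palindrome arithmetic, not a
detection failure.

## HGT candidates

Queries are aligned (seeded, BLOSUM62) against both partitions of a
labelled reference set; a missing side scores 0, `hU = B_out - B_in`, and
the call threshold `H = 30` score units follows the h-index convention of
the bdelloid HGT literature (configurable). "Unambiguous metazoan origin"
is operationalized symmetrically as `hU <= -H`. The linkage filter retains
a candidate only when its scaffold carries at least one unambiguous
metazoan gene, which removes contaminant-only scaffolds exactly and can
only ever decrease the candidate count. On synthetic genomes whose foreign
implants are exact copies of database records, precision and recall are
both 1.0 by construction of the validation, which is a correctness check
of the machinery — not evidence about sensitivity to diverged, genuinely
ancient transfers, where database coverage dominates.

## The synthetic-data generator: scope and limits

`simulate_haplotypes()` draws an i.i.d. ancestor (GC 0.5 by default) and
realizes each topology's divergence layers as substitutions only — no
indels, so the window algebra stays exact and coordinates are shared
across copies. Multiple hits within one k-window collide naturally; the
`(1-r)^k` term accounts for them. `implant_features()` inserts TE copies
(per-copy truncation and divergence drawn uniformly up to configurable
maxima, default 50% / 10%), gene cassettes and their reverse-complement
palindrome copies, foreign genes on host scaffolds, and contaminant-only
scaffolds — all as insertions into the collapsed haploid assembly (AB
collapses to one scaffold; other topologies emit one scaffold per
homoeolog group), so implants can never overlap and every truth coordinate
is exact. Genes are uniformly random ORFs (900 bp, standard code, frame 1):
downstream stages need identifiers, coordinates, strands and homology
signal, not realistic codon usage. Reads are single-end, uniformly placed,
with i.i.d. substitution errors and constant qualities; everything is a
pure function of (spec, seed).

Per-copy `read_templates` carry every implant, so one read set feeds all
stages. In polyploids, implants sit on one homoeolog group's scaffold and
therefore appear in reads at that group's copy number — biologically a
lineage-specific insertion. This is realistic for TEs but means that
heavily implanted polyploid toy genomes inflate apparent heterozygosity if
used for k-mer fitting; the heterozygosity validation therefore runs on
implant-free haplotypes, and polyploid implant studies should keep implant
load small relative to the genome.

What passing these validations shows: the estimators are correct on data
matching their generative assumptions, at desk scale. What they do not
show: robustness to indels, sequencing-quality structure, uneven coverage,
diverged-beyond-database HGT, fragmented assemblies, or repeat landscapes
of real genomes — the known failure modes of the underlying methods on
real data (assembly-dependent palindrome false positives from
mis-scaffolding chief among them) apply here unchanged.

## Problem sizes and reproducibility

The validation simulates 300 kb genomes at 15× per copy (error-free) for
heterozygosity recovery — relative errors within ±10% for `r` and ±5% for
`G` across five (ploidy, topology) pairs and `r ∈ {0.5%, 2%, 5%}` — 200 kb
at 20× for structure classification, 400 kb at 0.5× subsampling for TE
loads, and gene sets of ~60–100 for the palindrome and HGT stages; these
sizes give comfortable statistical headroom for every tolerance while
keeping the full suite in the minutes range on one CPU. All stages are
deterministic given seeds; `scripts/acceptance.R --seed N` reruns the whole
validation from one seed and writes every computed quantity to JSON.
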