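---
title: "Methods: small RNA profiling and lipid-metabolism miRNA screening in milkmiR"
author: "milkmiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling and lipid-metabolism miRNA screening in milkmiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkmiR)
```

# The analysis milkmiR implements

milkmiR is a small-RNA sequencing toolkit for the unreplicated two-library
design: one deeply sequenced small-RNA library per biological condition, as
used to compare primary mammary epithelial cells (pMECs) from a high-
(`HH`) and a low- (`LL`) milk-fat cow. The pipeline runs in seven stages:

1. **simulate** — generate a synthetic genome with planted miRNA/ncRNA
   loci and two read libraries with known differential expression
   (ground-truth data for every later stage);
2. **tags** — trim adapters, collapse reads to unique tags with
   per-library counts, filter to the 18–30 nt window, annotate tags
   hierarchically, and match them to known mature miRNAs;
3. **novel** — predict novel miRNA hairpins from genome-mapped tags with
   ten Drosha/Dicer duplex constraints;
4. **de** — normalized expression, log2 fold change, exact two-library
   p-value, FDR and significance label per miRNA;
5. **targets** — score miRNA–3′UTR complementarity with position-weighted
   penalty rules;
6. **enrich** — hypergeometric pathway/GO enrichment of predicted target
   sets;
7. **screen** — retain differentially expressed miRNAs whose predicted
   targets annotate to lipid-metabolism pathways and change in the
   opposite direction.

Each stage is an exported function; `runPipeline()` / `demoPipeline()`
orchestrate them with a manifest for reproducibility.

# Differential expression for two unreplicated libraries

## Normalization and fold change

Expression is normalized per library to reads per million:
$$\mathrm{std} = \frac{\text{count}}{\text{library total}} \times 10^6,$$
where the library total is the number of candidate-miRNA reads in that
library. Values below a floor of 0.01 (in particular zero counts) are
replaced by the floor so that the fold change
$$\log_2 \mathrm{FC} = \log_2\frac{\mathrm{std}_{LL}}{\mathrm{std}_{HH}}$$
is always defined; the published table this package reproduces prints
exactly this floored convention (an absent miRNA appears as 0.0100, and its
fold change is computed from the floored value). Both the floor and the
choice of denominator are configurable; the bundled reference rows
(`pmecTopTable()`) verify the arithmetic to 4 decimal places.

## The exact test

With a single library per condition there is no replicate-based dispersion
to estimate. The package uses the Audic–Claverie exact test, the standard
for comparing one tag's counts between two sequencing libraries: given $x$
reads in a library of $N_1$ total and a ratio $r = N_2/N_1$, the posterior
predictive distribution of the count $y$ in the second library is

$$P(y \mid x) \;=\; r^{\,y}\,
  \frac{(x+y)!}{x!\,y!\,(1+r)^{x+y+1}},$$

which is negative-binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$ — the implementation evaluates the tails with `pnbinom`
rather than term-by-term summation, and the test suite checks agreement
with direct tail summation to $10^{-10}$ over all $x+y \le 200$. The
two-sided p-value doubles the smaller tail (including the observed count)
and is capped at 1.

Significance labels follow the two-gate rule: `**` requires
$|\log_2 FC| > 1$ **and** $p < 0.01$; `*` requires $|\log_2 FC| > 1$ and
$0.01 \le p < 0.05$. On null simulations (2,000 miRNAs with equal means,
Poisson counts, ten seeds) the `**` rate is about 0.3%, driven almost
entirely by low-count miRNAs where a handful of reads can produce both a
large fold change and a small exact-test p-value; power at a true 4-fold
change with at least 50 expected reads is effectively 100%.

FDR is Benjamini–Hochberg across the tested miRNAs. The FDR column of the
published reference table is not reproducible from its own p-values by any
standard step-up procedure (rows with $p \approx 10^{-43}$ print FDR
values near 0.08), so FDR is reported but never used as a decision gate
here; the significance label depends only on fold change and p-value.

# Novel miRNA prediction

## Folding engine

Candidate precursors are folded with an interval dynamic program over
pseudoknot-free structures using stacking energies: a base pair contributes
GC −3, AU −2 or GU −1 kcal/mol *when stacked on an adjacent pair* (lone
pairs contribute nothing), and hairpin loops are at least 3 nt. This model
is deliberately simple — no multi-loop penalties, no dangling ends — but it
preserves the two properties the prediction criteria rely on: unpairable
sequence folds to energy 0, and energy decreases monotonically as
complementary stems lengthen, so an energy threshold separates real duplex
stems from background. The engine is deterministic (fixed decision order in
the traceback), implemented in C++ for the $O(n^3)$ recursion.

The energy scale runs hotter than a full nearest-neighbor model (a perfect
20-bp duplex scores around −50 here versus around −30 kcal/mol in
thermodynamic folders); the −18 kcal/mol threshold below is therefore a
loose gate in this model, and the duplex pairing constraints do most of the
discriminating.

## The ten constraints

`mireapParams()` holds the ten prediction constraints with the standard
Mireap defaults:

| constraint | default | interpretation here |
|---|---|---|
| minimal mature length | 18 nt | length of the most abundant tag at the locus |
| maximal mature length | 26 nt | |
| minimal star (reference) length | 20 nt | the duplex partner arm |
| maximal star length | 24 nt | |
| minimal cut-site depth | 3 reads | reads sharing the mature 5′ end |
| maximal copy number | 20 loci | genomic matches of the mature sequence ("20 nt" in the source convention is read as 20 loci) |
| maximal free energy | −18 kcal/mol | precursor fold energy (folding energies are negative, so this is $\Delta G \le -18$) |
| maximal duplex spacing | 35 nt | gap between mature and star arms |
| minimal duplex pairs | 14 | mature bases paired into the star arm |
| maximal duplex bulge | 4 nt | largest gap on either strand inside the duplex |

Two of these required interpretation. The "reference sequence length"
bounds (20–24 nt) are applied to the star arm, giving ten independently
testable constraints; and the cut-site depth is applied to the mature 5′
end only (where Drosha/Dicer processing leaves the sharpest read boundary).
Acceptance is the conjunction of all ten; the rejection tally names the
first failing constraint in a fixed canonical order and counts every
failing one, and a one-factor sensitivity suite verifies that each fixture
violating exactly one constraint is rejected for exactly that reason and is
admitted when that single parameter is relaxed.

## Candidate extraction

Tags are mapped to the genome by exact match on both strands; mismatched
mapping is out of scope (the synthetic data are generated from the same
genome, so exact matching is complete there, and sequencing-error tags
simply fail to map). Overlapping mapped tags are merged into loci with a
50 nt gap allowance so that both arms of one hairpin join a single locus;
the most abundant tag is the mature arm; 100 nt of genomic context on each
side is folded. The star arm is the span of the mature arm's pairing
partners on its dominant side (a folded flank can capture a stray mature
base; those pairs are not part of the duplex), and a read-supported star
tag overlapping that span overrides the inferred one. The precursor is
then re-folded on its own (mature through star) so that the free-energy
constraint scores the hairpin rather than the whole 220-nt window.
Windows overlapping known miRNA loci are excluded before filtering,
mirroring the convention that novel prediction follows the filtering of
known non-coding RNAs.

On synthetic data the planted novel hairpins with at least 10 mature-arm
reads are recovered completely at the demo scale. On hairpin-free
background, false discoveries are rare but not impossible: about 1 in 150
random candidate windows genuinely satisfies all ten constraints — we
cross-checked one such window with an independent thermodynamic folder and
its MFE was −20 kcal/mol, below the −18 threshold, i.e. random sequence
occasionally *is* a stable hairpin. Zero false discoveries over twenty
background seeds is therefore a high-probability outcome, not a
certainty.

# Target prediction and enrichment

## Position-weighted complementarity

The target scorer implements the penalty rules used by plant-style miRNA
target prediction: the miRNA (position 1 = 5′ end) is aligned against the
reverse complement of the candidate site; mismatches cost 1, G:U wobbles
0.5 and gaps 2, and every penalty is doubled over miRNA positions 2–13. At
most one gap is allowed, so sites are scanned at widths within one nt of
the miRNA length; ties break to fewer gaps, then the leftmost gap. A
perfect complement scores 0, and sites with penalty ≤ 4.0 are reported by
default. The dedicated search-engine scores of miRanda or TargetScan are
deliberately not re-implemented — the rule set above is the stated
criterion, and it is fully testable against an exhaustive alignment
enumeration oracle (equality over thousands of random pairs of length ≤ 12).

A note on strand symmetry: complementing both sequences does *not* leave
this score invariant in general, because complementation maps G:U wobbles
to C:A mismatches and the 2–13 weighting is anchored at the miRNA 5′ end.
The symmetric restriction (uniform weights, wobble-free windows) is
mirror-consistent and is what the test suite checks.

The positional filter applied on top (`schwabFilter()`) passes a site iff
there is no mismatch at miRNA positions 10–11, at most one mismatch within
positions 2–12, and no run of more than two consecutive mismatches; gaps
count as mismatches, wobbles do not.

## Enrichment

Term enrichment of a predicted target set is the one-sided hypergeometric
upper tail (via `phyper`) against a background that defaults to every
gene carrying at least one annotation term, with BH q-values across terms.
Annotation is always supplied as an input table (gene, term, category) —
the package ships no organism database.

# The lipid-metabolism screen

The screen formalizes the two-step selection applied to the pMEC
comparison: (i) keep differentially expressed miRNAs (label `*` or
stricter) with at least one predicted target annotated to a pathway of
interest — by default the four lipid pathways: fatty acid biosynthesis,
fatty acid elongation, glycerolipid metabolism, biosynthesis of
unsaturated fatty acids; (ii) keep a miRNA iff at least one such target
shows a *significant inverse* expression change. With one sample per
condition no correlation coefficient is computable, so "significant
inverse correlation" is operationalized as sign opposition with the
target's change significant at $p < 0.05$. Target expression is an input
table (in the motivating study it came from qPCR/Western blots), so any
gene-level log2FC + p table drives the screen. The original selection
started from a small random subset of the DE miRNAs; that step is not
algorithmic, so the implementation screens all DE miRNAs.

# The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which every property above is verified.

**Genome and loci.** Random uniform A/C/G/T chromosomes with three locus
classes planted without overlap (minimum 150 nt spacing so neighboring
fold windows stay distinct): known miRNA hairpins (which populate the
miRBase-style mature/hairpin references), novel hairpins (absent from the
references), and ncRNA loci. Hairpins are built as mature + loop (10–30
nt) + star, where the star is the reverse complement of the mature with at
most two substitutions and at most one engineered G:U wobble; every
planted precursor is folded at construction time and re-drawn until it
satisfies all ten prediction constraints, so recovery failures downstream
can only come from read sampling, not from the construction.

**Expression.** Per-miRNA expression weights are log-normal
(meanlog = log 400, sdlog = 1 — a heavy-tailed profile, as real libraries
show); 40% of planted miRNAs are differentially expressed at a true
log2FC of ±2 (LL over HH), the rest at 0, and the truth table flags DE
iff |log2FC| > 1. Because only ~25 loci stand in for thousands of real
miRNAs, the 22-nt modal read length is enforced by construction: weights
are drawn first and the loci carrying the top ~55% of read mass receive
22-nt matures, with the remaining lengths drawn from 20–24 nt.

**Reads.** Counts per arm are negative-binomial around the condition means
scaled to the target library size (size parameter 100, i.e. near-Poisson —
the downstream acceptance surface is the deterministic arithmetic, not the
noise model; `Inf` gives exact Poisson). Star strands are expressed at 10%
of the mature strand. 15% of each library comes from ncRNA fragments and
5% from random background positions, with fragment lengths peaked at the
configured mode. Reads get independent per-base substitution errors at
rate 0.001, then the fixed 3′ adapter is appended and the read truncated
to 36 nt. A fixed seed reproduces all output files byte-for-byte.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real base composition and repeat structure,
Illumina-specific error and quality profiles, isomiR 5′/3′ heterogeneity,
ligation biases, cross-mapping between paralogous miRNA families, and any
real annotation database. Results on synthetic data validate the
*arithmetic and the decision rules*, not organism-level biology.

# Numerical and design choices

* **Adapter trimming** is exact-prefix-suffix matching with a minimum
  overlap of 3 nt; without the floor, chance 1–2 nt matches at read ends
  would truncate tags.
* **Tag ordering** after collapsing is total count descending with
  lexicographic tie-break, so outputs are byte-reproducible.
* **Annotation priority** (miRNA > rRNA > tRNA > snRNA > snoRNA > repeat >
  exon > intron > unannotated) follows the common small-RNA pipeline
  convention and is configurable; each tag is assigned exactly one
  category (first match wins), which makes the annotation summary a
  partition whose read counts sum to the library totals.
* **Known-miRNA matching** is exact within the mature reference ± 2 nt of
  hairpin context, no mismatches, configurable.
* **Degenerate folds** (no pairing partner for the mature arm) yield a
  candidate with zero duplex pairs and infinite spacing, which fails the
  filter rather than erroring.
* **Ties in the fold traceback** are resolved in a fixed decision order;
  ties in best-site flagging go to the lowest score, then leftmost
  position.
* **Problem sizes** used by the test-suite and acceptance checks: the
  demo runs 1 chromosome × 100 kb with 20 known / 5 novel / 10 ncRNA loci
  and 50,000 reads per library (about half a minute end to end); the
  exact-test oracle grid covers all count pairs with $x+y \le 200$; DE
  calibration uses 2,000 null miRNAs × 10 seeds; scorer-oracle equivalence
  uses 1,000 random pairs. These sizes were chosen as the smallest at
  which every property is informative.

# Known limitations

* Exact-substring mapping only; genomes with sequencing-error reads or
  SNPs would need a mismatch-tolerant mapper in front of the candidate
  extractor.
* The folding model has no multi-loops penalties or dangling ends, and
  its energy scale is not calibrated to thermodynamic kcal/mol; the −18
  threshold is meaningful but loose in this model.
* One library per condition: the exact test captures sampling noise only;
  biological variability between animals is not modeled, which is an
  inherent limit of the design, not of the implementation.
* The FDR column of the bundled reference table has unknown provenance
  and is not reproduced.
* Target prediction scores complementarity only — no conservation, no
  site-accessibility or context scores.
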