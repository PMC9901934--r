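---
title: "Measuring mutational effects and epistasis in self-cleaving ribozymes"
author: "ribodms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mutational effects and epistasis in self-cleaving ribozymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement

A self-cleaving ribozyme cuts its own backbone only when it folds into its
native structure, so cleavage is an indirect readout of structure.
In a doped-library experiment, a chemically synthesized template pool
carries, at every position of the ribozyme, the reference base with high
probability (97%) and each alternative base with low probability (1%).
After co-transcriptional self-cleavage and template-switching reverse
transcription, every sequenced molecule reports two things at once: its
genotype, and whether it cleaved. A molecule that cleaved has lost its
5' leader (the upstream cleavage product); an uncleaved molecule retains
it.

`ribodms` implements the complete computational path from such reads to
per-genotype activity, pairwise epistasis and structure-mapped summaries,
together with a synthetic-read generator so that the whole pipeline can be
exercised and validated against a planted ground truth without any
external data.

## From reads to counts

Each read is `TSO pad + [leader if uncleaved] + mutated ribozyme`. The
variant caller slides a window of reference length `L` over the read and
keeps the offset with the fewest mismatches; ties go to the smallest
offset, and the mismatching positions/identities become the genotype.
Only substitutions are modelled — doped synthesis introduces substitutions,
not indels — and a read whose best window still has more than `max_muts`
(default 2) mismatches is set aside, though its mutation order is still
tallied in the mapping report. Reads are processed on the given strand
only; library orientation is fixed by the RT/PCR design.

A read is called **uncleaved** when the leader's 3'-terminal
`k = min(nchar(leader), offset)` bases exactly match the `k` bases
immediately 5' of the matched window; any mismatch there (for example when
only a TSO pad precedes the window) means **cleaved**. An optional
one-mismatch tolerance exists, off by default, because the experimental
definition is simple presence/absence of the cleavage product.

## Activity

For genotype `g` in replicate `r`,

$$\mathrm{FC}_{g,r} = \frac{N_\mathrm{clv}}{N_\mathrm{clv}+N_\mathrm{unclv}},
\qquad
\mathrm{RA}_{g,r} = \frac{\mathrm{FC}_{g,r}}{\mathrm{FC}_{\mathrm{wt},r}},$$

and the reported activity is the arithmetic mean of `RA` over replicates.
`RA` is not capped at 1: super-wild-type activity is meaningful. Replicate
observations with fewer than `min_reads` reads (default 10) are dropped,
and genotypes with no usable replicate are excluded and logged. A pooled
mode sums counts across replicates before computing FC; it is the right
choice when per-genotype depth per replicate is in the single digits, as
it is for double mutants in the bundled simulations (see below).

## Epistasis

For a double mutant `(i, j)`,

$$\varepsilon = \log\!\frac{\mathrm{RA}_{ij}}{\mathrm{RA}_i\,\mathrm{RA}_j}$$

(natural log by default, base configurable). Zero is the additivity point
of the multiplicative model; a compensatory pair that restores a broken
base pair gives $\varepsilon > 0$, and a second hit in an already
destabilized stem typically gives $\varepsilon < 0$. All three RAs are
floored at `1e-3` before the logs so that zero-count genotypes yield large
but finite values; the floor is recorded in the output.

Sampling noise can fake epistasis when the double's RA is close to a
constituent single's. The reliability filter pools the differences
$d = \mathrm{RA}_{ij} - \mathrm{RA}_k$ over all doubles and both
constituents, takes $\sigma = \mathrm{sd}(d)$, and flags a record when
either difference is smaller than $c\,\sigma$. The filter constant is
exposed as $c \in [1, 3]$ with default 1, and the either/both combiner is
configurable, because the procedure admits a family of reasonable
calibrations; both settings are echoed in output headers.

## Structure mapping

Two distinct predicates are used deliberately:

* **Mismatch categories** (per stem): a double mutant whose positions are
  both base-paired positions of a region is categorized by the number of
  touched pairs left as mismatches — `WC_GU` (zero: every touched pair is
  Watson-Crick *or G:U wobble*), `one_mismatch`, `two_mismatch`.
* **On-diagonal** (per stem): partner-position doubles whose resulting
  pair is strictly Watson-Crick. Wobble-restoring doubles go off-diagonal.
  In the position-major heatmap these doubles sit on a stem's
  anti-diagonal, except where the original pair is non-canonical (the
  U:U pseudoknot pair in the CPEB3-like reference), in which case the
  category predicate still applies naturally.

Doubles spanning two different paired regions are `not_in_region` for
every region; a cross-region analysis exists for exploration but is not
part of the shipped summaries.

Distribution comparisons use the Mann-Whitney U test: full enumeration of
group assignments for small samples (ties handled by mid-ranks; identical
samples give p = 1), the exact tie-free distribution up to
$mn \le 10^4$, and otherwise a normal approximation with tie and
continuity corrections. Two-sided p-values are twice the smaller tail,
capped at 1.

## Duplex free energies

Each paired region is split into its two strands, keeping only the
base-paired nucleotides; the free energy of their duplex at 37 °C is
duplex initiation plus the sum of nearest-neighbor stacking terms, plus
terminal AU/GU penalties and the symmetry correction for
self-complementary duplexes. Terminal-loop contributions are deliberately
ignored so terminal and internal stems are comparable; the bimolecular
initiation term is constant across regions and therefore cancels from any
correlation across regions.

The embedded parameter table is the Turner-rules set (Watson-Crick stacks
from Xia et al. 1998, G·U stacks from Mathews et al. 1999, as tabulated in
the Turner 2004 collection). This set was chosen over the older
Serra–Turner 1995 tabulation because its values are independently
verifiable against ViennaRNA's evaluator, which ships the same family —
the package's test suite checks every shipped region's duplex energy
against `RNAeval` to within 0.5 kcal/mol. Region rankings, which are all
the stability correlation uses, are insensitive to this choice. Regions
containing a non-canonical pair (the U:U pseudoknot pair) have no
nearest-neighbor duplex energy and are reported as `NA` and excluded from
the correlation.

The stability correlation is Pearson's r between each region's duplex
free energy and the median replicate-mean RA of all single mutants at the
region's paired positions; at least three regions are required and a
constant-median configuration is reported as degenerate rather than
correlated.

## The synthetic data generator

The generator emulates the statistical structure of the doped-library
experiment: per-position multinomial doping (97/1/1/1), three replicates,
four seeded TSO pads of lengths 3–6 cycled read by read (a pad that
happens to equal the leader's terminal bases would make cleaved molecules
look uncleaved, so such pads are redrawn — the experimental TSOs are
likewise designed to be distinguishable), cleavage decided per molecule as
Bernoulli(FC), and standard 4-line FASTQ output in DNA alphabet with
constant quality. Identical configurations produce byte-identical output.

The planted activity model is structure-aware: catalytic mutations
abolish activity and admit no rescue; a mutation that breaks a base pair
is strongly deleterious (`stem_single_effect`, default 0.2, scalar or
per-region); a loop mutation, or a stem mutation that leaves the pair
Watson-Crick/wobble, is mild (`loop_single_effect`, 0.8); a partner-pair
double that restores pairing is multiplied back up
(`compensatory_bonus`, 25, so a broken-then-restored pair returns to
RA 1); and a double that disrupts two pairs of the same stem takes an
extra penalty (`double_disruption_penalty`, 0.5), reflecting the
cooperativity of helix stability. The wild type always receives `wt_fc`
exactly; defaults use 0.90, and the bundled twister-like analyses plant
0.60, the values printed for those constructs. Genotypes of order three
or more receive multiplicative single-mutant effects, clamped — they are
sampled, counted, and excluded from analysis.

What the generator does **not** emulate: PCR and synthesis bias, jackpot
duplicates, unequal replicate pooling (exposed but defaulting to equal),
sequencing errors (exposed via `error_rate`, default 0 — the experimental
analysis never models them, and a nonzero setting exists to stress-test
the caller), paired-end structure (reads are already "joined"), and
kinetics (a single fixed-time readout by design). Passing recovery tests
on simulated data therefore validates the *computational* path — calling,
classification, normalization, epistasis, filtering, structure mapping —
not robustness to these experimental artifacts.

## Shipped reference definitions

The five reference definitions (`*_synthetic.yaml`) are constructed
stand-ins, not the published constructs: the published figures carry the
sequences and exact pairings, and those are not reproducible from text.
The stand-ins match everything the text pins down — lengths 69/87/48/71/45
nt; region inventories (CPEB3-like and HDV-like P1–P4 plus pseudoknot T1,
twister-like P2/P4/T1/T2, hairpin-like P1–P3, hammerhead-like P1/P2);
stated stem sizes (3-bp P3s, 14-bp HDV P4, 4-bp twister T1, one-pair U:U
CPEB3 T1, 2-bp HDV T1); and catalytic identities with their figure
numbering (C57, C75, A1/G39, G29/A59, G25/G39). Every analysis accepts
user-supplied definitions in the same YAML format, so real constructs are
a drop-in replacement.

Coordinates are 0-based and anchored at the cleavage site; each file
carries a `display_offset` for figure-style labels. The hammerhead
construct's catalytic "-1C" lies in the leader, outside the ribozyme
frame, and is documented in the fixture rather than renumbered.

## Numerical and design choices

* The epistasis formula's printed form is ambiguous in the source
  material; the log-ratio reading is the only one consistent with
  positive/negative epistasis semantics, and the additivity point is 0
  (the alternative "greater than 1" convention is not used). A
  `|epsilon| > 1` threshold is a useful rule of thumb for "strong".
* The filter clause is likewise not readable as printed; both the
  constant and the combiner are exposed and logged rather than guessed.
* Whether epistasis uses replicate-mean RA or per-replicate RA averaged
  afterwards is unspecified; replicate-mean RA is the default (matching
  the stated order of operations), the other mode is available.
* Class-average FC summaries are unweighted means over genotypes;
  depth-weighted means are a flag.
* Axis and enumeration order is fixed A<C<G<U skipping the reference
  base; tie-breaks in the caller go to the smallest offset. Both are
  arbitrary but deterministic.
* Simulation scale: the bundled analyses use 3 replicates x 1e5 reads.
  At that depth the wild type is ~23,000 reads deep per replicate and
  every single mutant ~240, but a specific double mutant is expected only
  `0.01^2 * 0.97^(L-2) * n` ≈ 2.5 times per replicate — hence the pooled
  counting mode, and hence a fraction `exp(-7.4)` ≈ 6e-4 of doubles is
  expected to be absent from a run altogether. Complete double coverage
  and tight double-mutant statistics require read counts in the millions,
  as in the original experiments; the bundled scale keeps a full run in
  tens of seconds while leaving singles-level recovery sharp.

## Known limitations

* Substitutions only; indel-bearing reads are unassigned.
* The sigma filter at shallow double-mutant depth preferentially removes
  exactly the low-contrast records, so post-filter category distributions
  are survivor-biased; category summaries can be computed pre-filter
  (`drop_filtered = FALSE`) and the on-diagonal/compensatory conclusions
  are robust to the choice.
* Duplex energies ignore loop entropy, dangling ends and coaxial
  stacking; they are comparative quantities, not folding predictions.
* The Mann-Whitney normal approximation is used above the exact regimes;
  its agreement with enumeration is tested at the boundary.
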