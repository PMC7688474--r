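---
title: "Species-level 16S profiling with homologous species groups: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-level 16S profiling with homologous species groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsg16S)
```

## The model

Short 16S hypervariable regions carry real taxonomic signal down to the
genus, and partial signal below it. `hsg16S` treats the two regimes
differently:

* **Genus and above** is a classification problem with abundant, mostly
  unambiguous training data, handled by a naive Bayes word-presence
  model with bootstrap confidence.
* **Species** is a *resolution* problem: some species are separable by
  the region and some provably are not. Instead of pretending otherwise,
  the package models each species by a consensus sequence of its strains
  and groups species whose consensus sequences are ≥ 99% identical into
  *homologous species groups* (HSGs) — connected components of the
  pairwise identity graph. Assignment then happens at the finest honest
  level: a specific species when the nearest consensus is a singleton
  group, the group label (`"name+"`) when it is not, and `unclassified`
  when no hit clears the gates.

The package assumes amplicon reads are substitution-dominated (Illumina
chemistry), that reference lineages can be reconciled through a single
canonical taxonomy, and that a species' strains are similar enough for a
center-star alignment to be an adequate multiple alignment (true at
within-species divergences of a few percent; the star heuristic is not a
general-purpose MSA).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| primer pair | 337F/806R (V3–V4) | IUPAC | the printed V3–V4 pair; V1–V2 primers are not shipped because their sequences are user-supplied |
| primer error budget | 0.2 × primer length | edits | 2–3 nt for 17–19-nt primers; edit distance (with indels), mirroring cutadapt's error model |
| fragment length filter | mean ± 2 sd, two-sided | nt | region fragments |
| database length filter | mean ± 3 sd, two-sided | nt | full-length reference sequences |
| merge policy | overlap 20–300, mismatch ratio ≤ 0.25 | bp | FLASH defaults with the stated overlap bounds |
| merged-read filter | length ≤ mean + 2 sd, upper only | nt | only the upper bound is applied to merged reads (V3–V4: 421 + 22 = 443) |
| alignment scoring | +5/−4, gap 10 + 0.5/extra, free end gaps | — | EMBOSS needle DNA defaults, endweight false |
| HSG threshold | 99 | % identity | species at or above it are indistinguishable by the region |
| HSG scope | within genus | — | 16S indistinguishability is a within-genus phenomenon; an all-vs-all switch exists |
| OTU threshold | 0.99 | fraction | identity over the shorter sequence, cd-hit convention |
| species gate | > 97 (strict), e-value < 1e−10 | % / — | k = 1 nearest neighbour; the identity gate is primary |
| classifier | w = 8, 100 trials, 1/8 subsample, threshold 0.8 | — | the standard word-presence bootstrap scheme and reporting convention |

## Numerical choices

**Alignment tie policy.** Optimal-score alignments are not unique, and
different optima can have different identity percentages. The aligner
therefore optimises a lexicographic objective — score, then number of
identical columns, then shorter alignment — every component of which is
invariant under swapping the sequences. This makes reported identity
deterministic *and* symmetric; the test-suite oracle (an independent
plain 3-state DP in R) implements the same contract and must agree
exactly. Terminal gaps are free but still count in the identity
denominator, exactly as in needle with `endweight` off: a one-base
terminal overhang on a 4-base alignment costs 25 identity points. One
consequence worth knowing: for short sequences a shifted
"staircase" alignment with free tails can legitimately outscore the
intuitive no-gap alignment.

**Equal-length fast path.** Greedy OTU clustering and the consensus
search compare hundreds of reads against hundreds of references. For
equal-length pairs the implementation uses ungapped (Hamming) statistics
with early exit: under the needle scoring a gap pair costs at least 20
while a substitution costs 9, so at the ≥ 97% identity regimes the gates
care about, the optimal alignment of equal-length sequences is ungapped
and the fast path is exact. Unequal-length pairs always run the full
affine-gap DP.

**Ties elsewhere.** Consensus columns: most frequent non-gap residue if
it reaches half the rows, else `N`; ties pick the lexicographically
smallest residue; `N` never counts as identical downstream. Classifier
argmax ties break to the lexicographically smallest genus — bootstrap
confidence is therefore *confidently wrong by convention* on degenerate
models (e.g. two genera trained on byte-identical sequences), which is
the price of bit-reproducible output; ambiguity between genuinely
distinct genera still shows up as low confidence. Equal-best species
spanning different groups resolve to the lexicographically smallest
group label with the tie count reported. cd-hit representative ties go
to the earliest-founded cluster.

**Degenerate inputs.** Ambiguity codes are permitted in primers (matched
by expansion intersection) and score −2 against everything in
alignments. Records resolving nowhere in the taxonomy are flagged, never
dropped silently; a species whose region cannot be extracted aborts read
simulation with the species named, mirroring how real primer failures
(e.g. archaeal taxa with 806R) should surface. The merged genus label
`Escherichia.Shigella` is not an NCBI name, so the resolver maps it back
through *Escherichia*; without this, re-annotating an already
re-annotated table could silently coarsen records to family rank and
idempotence would fail.

## What the synthetic generator emulates — and what it does not

The generator builds: a seven-rank toy taxonomy (taxdump dialect);
full-length 16S-like references (conserved pads, instantiated degenerate
primer sites, a 400-nt species core); planted HSGs (members derive from a
group leader at 0.5% divergence); guaranteed between-species separation
(each species mutates a disjoint 8-position block of a shared per-genus
backbone, giving ≥ 4% pairwise divergence, against the 2% the tests
require); strains at Binomial(L, 0.002) divergence; communities under
uniform, linear and power-law (`a_i ∝ i^(-p)`) rank-abundance models
over a seeded random species order; 16S copy numbers uniform on 1–10;
and reads as exact region copies with i.i.d. substitutions at 0.5%
(optionally as overlapping 250-nt pairs at constant Q40).

It deliberately does **not** emulate: indel or quality-profiled
sequencing error, chimeras, length variation between species cores (all
cores are 400 nt — real V3–V4 lengths vary with sd ≈ 11 nt), genome
length bias, intragenomic 16S heterogeneity, or taxonomies with merged or
deleted nodes. A green test therefore establishes that the *method* is
implemented correctly and recovers a stated world exactly; it does not
establish robustness to real-data pathologies like chimeric reads or
reference mislabelling. A fully degenerate world (zero divergence
everywhere, every species collapsing into one group per genus) is
intentionally unrepresentable: the spec constructor rejects a separation
of zero because the planted-group contract would be meaningless there.

## Design choices where the design was open

* **Homonym resolution**: a label mapping to several taxids keeps only
  candidates whose node rank equals the rank being searched; if that
  leaves more than one, the rank is skipped. This mirrors
  skip-on-failure behaviour without guessing between homonyms.
* **`sp.`-type labels** carry no species information and fall through to
  the genus; a named species under an unannotated genus is cleared,
  because both group naming and classifier training key on the genus.
* **Population standard deviation** for length filters (database-scale
  statistics; a fixed, testable choice), with closed (inclusive)
  interval bounds.
* **Identity, not similarity**: group edges use the aligner's identity
  percent over the full alignment length, gap columns included.
* **E-value surrogate**: `E = K·m·n·exp(−λS′)` with `(λ, K) =
  (0.625, 0.41)` and `S′` the alignment rescored at +1/−2. It stands in
  for BLAST's database-scale statistics, is monotone in score and linear
  in either length, and can be disabled; the identity gate does the real
  work.
* **Read-proportional abundance** with an explicit `unclassified` bin —
  no copy-number correction, and nothing silently dropped, so
  per-sample profiles always sum to 1 and read conservation is auditable
  from the logs.
* **No BLAST seeding, no cd-hit word filter**: consensus databases are
  small enough for exhaustive comparison, which removes heuristic
  variance from a result-bearing computation.

## Known limitations

Greedy clustering is order-dependent by construction (length-descending,
stable), exactly like the tool it models. The center-star MSA can place
gaps suboptimally for divergent members; at the ≤ 1% within-species
divergences the consensus model targets this has no effect, but the
package should not be used to align distant homologs. The naive Bayes
classifier shares the well-known limits of word-presence models: closely
related genera with near-identical regions are separated only by the
handful of discriminating words, and its confidence is a bootstrap
agreement, not a calibrated probability. Finally, HSGs are
region-specific: a group built from V3–V4 says nothing about
separability in V1–V2 or the full gene.
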