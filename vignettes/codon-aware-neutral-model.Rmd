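---
title: "A codon-aware neutral model for somatic missense severity"
author: "codonNeutral"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A codon-aware neutral model for somatic missense severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonNeutral)
```

## Motivation and model

Gene-level tools for somatic mutation interpretation tend to look either at
amino-acid conservation (is this substitution biochemically severe?) or at
nucleotide-level mutation rates (is this base change likely?), but not both
at once. Yet the two interact: which amino-acid changes are *reachable*
from a wild-type codon by one nucleotide substitution, and how likely each
is, depends entirely on the codon's spelling. A cohort of tumour variants
can only be called "more radical than chance" against a null that knows
this.

`codonNeutral` builds that null. For a gene model with codons
$c_1,\dots,c_L$ and protein $a_i = T(c_i)$ (standard genetic code), the
neutral event set $E$ consists of every single-nucleotide substitution in
the codons of interest whose translation (i) changes the amino acid and
(ii) does not create a stop codon. A codon has exactly nine
single-nucleotide neighbours; synonymous and stop-gain neighbours are
excluded, so a codon contributes between 0 and 9 missense events (tryptophan's
TGG, for example, contributes 7: two of its neighbours are stops). Each
event $j$ with base change $b \to b'$ carries

* a raw weight $\tilde p_j = w_{b \to b'}$ from a 12-entry base-substitution
  signature,
* a probability $p_j = \tilde p_j / \sum_m \tilde p_m$, normalized over the
  **whole table**, not per codon — the null is one categorical distribution
  over all events,
* a BLOSUM62 score $S_j = B(A_j, A'_j)$, and
* a radical indicator $R_j = \mathbf 1\{S_j \le 0\}$.

The expected severity under neutrality is $\sum_j p_j S_j$ and the expected
radical fraction $\sum_j p_j R_j$ (`neutralSummary()`). An observed cohort
of $N$ validated missense variants gives $\mu_{obs}$ (mean score) and
$r_{obs}$ (radical fraction); Monte Carlo replicates of size $N$ drawn from
$\mathrm{Categorical}(p_1,\dots,p_J)$ give the null distribution of those
summaries and one-sided empirical p-values.

### Assumptions

* Somatic missense variation arises from single-nucleotide substitutions;
  multi-nucleotide and indel events are out of scope.
* The mutational process is summarized by 12 strand-specific base-change
  weights applied to the coding strand as written. There is no
  reverse-complement symmetrization and no trinucleotide (flanking-context)
  dependence; a context-dependent signature can only be approximated by its
  marginal single-base rates.
* Events are exchangeable across positions given the weights: the null has
  no positional hotspots. Deviation in *severity* and deviation in
  *location* are therefore tested separately (Monte Carlo tails vs the
  domain goodness-of-fit tests).
* BLOSUM62 measures evolutionary conservation of the substitution, not
  direct functional impact.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `weights` | `"uniform"` | 12 base-substitution weights; presets `"uniform"` and `"titv"` (transitions weighted `kappa = 2`), or any user signature via `substitutionWeights(values=)` / `readSubstitutionWeights()`. Only ratios matter. |
| `radicalThreshold` | 0 | inclusive cutoff for the radical flag, $S \le$ threshold. |
| `positions` | observed codons | event space: the codons mutated in the cohort (the default pipeline behaviour) or the whole CDS (`whole_cds: true`). |
| `M` | 7600 | Monte Carlo replicates; at this depth the p-value Monte Carlo SE is at most $0.5/\sqrt{7600} \approx 0.006$. |
| `correction` | `"none"` | p-value estimator; `"add-one"` uses $(1+\text{count})/(M+1)$ and never returns exactly 0. |
| `onMismatch` | `"error"` | wild-type mismatches between cohort and CDS: hard error, or skip-with-warning for cohorts mixing transcript isoforms. |

The two weight presets are deliberately generic placeholders for a
mutational process. Tumour-type-specific signatures (e.g. a breast
adenocarcinoma substitution spectrum) are not shipped: they are study
inputs, and results — especially the neutral mean score and radical
fraction — depend on them. Any 12-entry signature file can be supplied.

### Design decisions in the definitions

* **Radical means $S \le 0$, inclusive.** Score 0 substitutions (e.g.
  Arg→His) count as radical. The threshold is exposed as an argument for
  sensitivity analysis rather than hard-coded.
* **Ties count in both tails.** The inequalities are non-strict
  ($\mu_s \le \mu_{obs}$, $r_s \ge r_{obs}$), and the opposite
  (conservative-direction) tails are always computed with the reversed
  non-strict inequalities, so $p + p_{opposite} \ge 1$ with equality only
  without ties. Both tails are always reported: oncogenes with
  structure-preserving activating mutations sit in the conservative tail,
  tumour suppressors in the radical tail, and reporting one tail only would
  silently hide half the biology.
* **Zero-weight events are retained** with $p_j = 0$, so the event count
  $J$ is a pure function of the codon content and never of the signature's
  sparsity.
* **Stop gains are excluded from $E$** and, symmetrically, observed
  nonsense variants are counted but never scored — BLOSUM has no stop row,
  and mixing truncations into a substitution-severity statistic would
  conflate two different lesion types.
* **One event per distinct (case, protein change)** by default when reading
  cohort tables: paired biospecimens from one case reporting the same call
  are one observation. A variant recurring across many cases counts once
  per case — cohort frequency is exactly what the test weighs.

## The synthetic-data generator

`makeToyGene(L, seed)` draws a start codon followed by $L-1$ codons uniform
on the 61 sense codons; `makeCohort()` draws $N$ events from the gene's
whole-CDS neutral table with probability $\propto p_j\,
e^{\beta S_j}$ and formats them as a MAF-lite table, replacing a
binomial($N$, `nonsenseRate`) subset with single-nucleotide stop gains. The
exponential tilt is the minimal one-parameter family that produces both
radical-shifted ($\beta < 0$, tumour-suppressor-like) and
conservative-shifted ($\beta > 0$, oncogene-like) cohorts while reducing to
the exact neutral distribution at $\beta = 0$. It is a test fixture, not a
model of tumour selection.

Defaults are chosen once at study scale: $L = 500$ codons (a mid-sized
oncogene CDS), $N = 200$ events (the order of the per-gene cohort sizes a
1000-case breast-carcinoma exome cohort yields for its most mutated genes),
$M = 7600$ replicates (the depth used for the convergence diagnostics),
nonsense admixture 5% (a typical missense:nonsense mix for genes without
strong truncation selection).

What the generator does **not** emulate, and what passing tests therefore
do not establish about real data: positional hotspots (real oncogenes
concentrate mutations at a few residues; the tilt shifts severity, not
location), realistic codon usage (uniform sense codons), trinucleotide
signature structure, transcript-isoform ambiguity in HGVSp labels, and
sequencing artefacts. Tests built on the generator validate the
*statistical machinery* — enumeration, normalization, calibration, tail
direction — not the biological calibration of any particular signature.

## Numerical choices

* Event probabilities must sum to 1 within $10^{-12}$ (validity check on
  the table); normalization is a single division by the raw-weight total.
* Categorical sampling uses R's `sample.int(J, N * M, replace = TRUE,
  prob = p)`; a run is fully determined by the integer seed, and every
  randomized entry point (`simulateReplicates`, `makeToyGene`,
  `makeCohort`, the CLI) takes one.
* Goodness-of-fit: neutral probabilities are renormalized over the tested
  categories before computing expected counts (a proper multinomial null
  requires probabilities summing to 1; published domain tables often print
  fractions that do not, and the renormalization is announced via
  `message()`). Zero-observed categories stay in the test — their
  chi-square contribution is $E_d$ and their G contribution is 0 by the
  $0\log 0 = 0$ convention. A zero *expected* count is an error instructing
  category merging, since both statistics are undefined there.
* Domain tables report a domain with no observed mutations as mean 0 with
  an explicit `observed_empty` flag (the mean is undefined; 0 is a print
  convention, and downstream code should consult the flag). A domain with
  observed mutations but zero neutral mass is flagged rather than fatal.
* Convergence diagnostics reuse one replicate stream and evaluate nested
  prefixes of the grid, flagging successive estimates more than 3 pooled
  Monte Carlo SEs apart; the default grid ends at $M = 7600$.
* A terminal stop codon on a CDS is stripped (and recorded); an internal
  stop is a hard error naming the codon, because no wild-type protein is
  defined. The CDS FASTA can be cross-checked against a protein FASTA at
  load time.

## Problem sizes in the shipped tests

The test suite exercises: brute-force oracle equivalence of the enumerator
on 100 random genes of up to 50 codons (the oracle mutates the raw CDS
string and re-translates whole sequences independently of the enumeration
path); p-value calibration with 500 neutral self-test trials at $N = 50$,
$M = 500$, checked against uniformity with a lattice-aware
Kolmogorov–Smirnov bound (one-sided empirical p-values on a discrete
statistic are superuniform, with KS distance bounded by the largest atom of
the null lattice); tilt-direction recovery over 100 seeded cohorts per
direction at $\beta = \pm 2$, $N = 200$; and bit-identical end-to-end
reproducibility of the pipeline bundle at $L = 500$, $N = 200$,
$M = 7600$. These sizes were chosen as the smallest at which each property
is sharply testable.

## Known limitations

* Results are conditional on the supplied signature weights; with the
  shipped placeholder presets the neutral means are generic, not
  cohort-calibrated.
* The default event space restricted to observed codons makes the null
  *conditional on where mutations landed*; whole-CDS mode answers a
  subtly different question (severity relative to everything the gene
  could have produced), and domain fractions differ between the modes.
  Both are provided; reports should state which was used.
* No splice-site, indel, multi-nucleotide or cDNA-level (HGVS "c.")
  variant support; no transcript selection — the CDS supplied is the CDS
  tested.
* Per-residue hotspot and positional clustering statistics are out of
  scope; the domain tests are the coarsest useful location readout.
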