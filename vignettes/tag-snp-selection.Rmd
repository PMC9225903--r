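---
title: "Tag SNP selection by fuzzy LD clustering and constrained binary PSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag SNP selection by fuzzy LD clustering and constrained binary PSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(snptag)
```

## The model

`snptag` selects a fixed-size panel of tag SNPs from `n` phased
haplotypes over `m` biallelic loci, coded 1 for the major allele, 0 for
the minor allele and `NA` for missing calls. The selection problem —
pick `S` loci whose genotypes best predict the other `m - S` — is
NP-hard, so the package works in two stages: an LD clustering stage that
shrinks the search space to one candidate per equivalence class of
correlated loci, and a discrete swarm optimizer over those candidates.
The working assumption throughout is block-structured LD: loci fall into
segments with few distinct haplotype patterns, so within-segment loci
carry nearly the same information and one representative suffices.

### LD as a fuzzy relation

For loci `i` and `j` with major-allele frequencies `f_A`, `f_B` and
joint major-major frequency `f_AB`, the raw disequilibrium is
`D = f_AB - f_A f_B` and the reported similarity is Lewontin's
normalized `|D'| = |D| / D_max`, where `D_max` is
`min(f_A f_b, f_a f_B)` for `D > 0` and `min(f_A f_B, f_a f_b)` for
`D < 0`. Written with the sign carried by `D` alone, both branches keep
the value in `[0, 1]`, which the downstream thresholding requires. Two
degenerate cases return 0 by convention: exact independence (`D = 0`)
and a locus monomorphic in the pairwise-complete subset (`D_max = 0`, no
association signal to normalize). Missing data are handled
pairwise-complete: a haplotype contributes to the `(i, j)` entry only if
it observes both loci.

The matrix `R` of pairwise `|D'|` values with unit diagonal is a fuzzy
similarity relation (reflexive, symmetric). It is generally not
transitive, so it is closed under max–min composition: the fuzzy
Warshall sweep `r(i,k) <- max(r(i,k), min(r(i,j), r(j,k)))` over
intermediate loci `j` yields the transitive closure `t(R)`, the smallest
fuzzy equivalence relation above `R`, in one `O(m^3)` pass (the package's
test suite cross-checks it against repeated max–min self-composition to
a fixpoint, which is the defining construction). The λ-cut
`t(R) >= λ` is then a crisp equivalence relation for *any*
λ, and its classes partition the loci; as λ decreases the partitions
only merge (they are nested), which the suite verifies across a grid of
cut levels. The comparison is a plain `>=` without tolerance: closure
entries are exact maxima/minima of input values, so no floating-point
slack accrues.

Each class contributes one candidate tag: the member with the largest
sum of `|D'|` to its classmates, computed from the *original* `R` rather
than the closure. The closure inflates within-class values toward the
chain strength and would flatten the ranking; the raw similarity keeps
the "most central locus" reading. Ties go to the lower locus index for
determinism. The class size attached to each candidate — how many loci
it represents — is the currency of the optimization stage.

### The constrained binary swarm

Particles are bit vectors over the candidate set `SI`; a set bit selects
that candidate as a tag. The fitness of position `X` is
`f(X) = (1/m) * sum of |clu_j|` over selected candidates `j`: the
fraction of all loci represented by the selected tags' classes. Because
every particle is repaired to exactly `S` set bits, the tag count needs
no penalty term in the fitness.

The run is split into two phases at `switch_fraction * max_iter`
(default 0.5 — the rules themselves specify only "early" and "late", so
the boundary is exposed as a parameter and split symmetrically by
default):

* **Early phase** (exploration): classic binary-PSO rules. Velocity
  `v <- w v + c1 rand (pbest - x) + c2 Rand (gbest - x)` with
  independent per-component uniforms, clamped to `[-v_max, v_max]`;
  the sigmoid `1/(1+exp(-v))` gives the probability that the bit is set
  to 1 regardless of its current value.
* **Late phase** (exploitation): the inertia term is dropped, so
  velocity is pure self- plus social cognition and vanishes exactly at
  consensus (`x = pbest = gbest`). The probability map is folded:
  `|2/(1+exp(-v)) - 1|`, which is 0 at `v = 0` and saturates to 1 as
  `|v|` grows. A bit then flips only in the direction of its velocity
  sign — to 1 for `v > 0`, to 0 for `v < 0` — and stays put at `v = 0`
  or when the draw fails. A swarm whose particles all sit on the
  incumbent is therefore a fixpoint, which is the intended late-stage
  behavior: settle rather than skip over the optimum.

Two corner cases of these rules are pinned down explicitly: the
late-phase "else" branch for negative velocity retains the previous
position (sending it to 1 would contradict the symmetric
positive-velocity rule and reintroduce the skipping the late phase is
meant to suppress), and the under-size repair flips bits from
0 to 1 (the only direction that can increase the count). Repair itself
is deterministic and greedy: over-size positions keep the `S` selected
candidates with the largest class sizes, under-size positions switch on
the largest unselected ones, ties to the lower index. Personal and
global bests update on strict improvement only, so the incumbent fitness
history is non-decreasing — asserted on every run in the test suite.

Defaults (`pop_size = 30`, `max_iter = 200`, `c1 = c2 = 2`, `w = 1`,
`v_max = 4`) are the canonical binary-PSO settings; all are exposed via
`swarm_config()`. On 12-candidate instances with `S = 4` the swarm
recovers the exhaustive optimum over all 495 subsets in essentially
every seeded run (the acceptance suite requires 18 of 20) — unsurprising,
as the greedy repair alone already climbs toward large classes; the
swarm's value shows when class structure and `S` interact less cleanly.

### Scoring by leave-one-out imputation

A tag set is only as good as its reconstruction of the non-tag loci.
`loocv_accuracy()` holds out each haplotype in turn, trains one binary
C-SVC (RBF kernel) per non-tag locus on the remaining haplotypes —
features are the tag genotypes, the label is the locus's genotype — and
scores `Acc = 1 - sum |s - s'| / comparisons`. With complete data the
denominator is exactly `|O| * N`. The haploid 0/1 coding makes each
per-locus error 0 or 1, so `Acc` is guaranteed to lie in `[0, 1]`
(diploid 0/1/2 coding would break that and is out of scope). A non-tag
locus constant in training is predicted as that constant without
fitting; identical training labels share one fitted model per fold via a
cache, which is an exact shortcut, not an approximation.

SVM defaults are `gamma = 0.07` and `cost = 7`: a kernel width well
below 1 suits 0/1 features (pointwise distances are small integers), and
a moderate soft-margin cost tolerates label noise without memorizing it;
both are configurable in `impute_config()`. Features are
not rescaled (`scale = FALSE`): inputs are already 0/1 and rescaling
would make fits depend on fold composition.

Missing data: training-side missing entries are imputed with the locus's
major allele computed on the training rows (policy `impute_major`;
`drop_sample` is available), and missing non-tag calls of the held-out
row are excluded from both the error sum and the denominator, keeping
the accuracy well-defined and in range under missingness.

One reading choice: cross-validation folds are haplotype rows, not
individuals. A phased VCF contributes two rows per sample, and the two
rows of one individual can then appear on opposite sides of a fold
split; with unrelated samples and phased data the effect is small, but
row-level folding is the simpler, stated contract.

## The simulator and what passing tests mean

`simulate_haplotypes()` emulates exactly the structure the method
assumes: per block, a small set of founder patterns; per haplotype, an
independent founder choice per block (free recombination between
blocks); then i.i.d. allele flips (`mutation_rate`) and masking
(`missing_rate`). Founder sets are constrained to segregate at every
locus — each within-block column is drawn uniformly over the
non-constant configurations of the founder set, so with two founders the
pair is complementary. A locus fixed in the founders would be
monomorphic, i.e. not a SNP at all, and would sit in LD 0 with
everything, making "recover the true blocks" ill-posed; the constraint
is therefore both the biologically right definition and what makes block
recovery a meaningful test. `founders_per_block = 1` remains available
to exercise the monomorphic degenerate path deliberately.

Default study conditions, used by the acceptance checks and the
`scripts/acceptance.R` report: 200 haplotypes, 4 blocks of 5 loci, 2
founders per block, λ = 0.8, `S = 4`, with noise either 0 or a 2%
allele-flip rate over 20 seeded replicates. At zero noise the 4 classes
are exactly the 4 blocks, the forced solution tags one locus per block,
and LOOCV accuracy is exactly 1.0 (every non-tag locus is a function —
identity or complement — of its block's tag). At 2% noise the observed
accuracy sits near 0.96–0.97: the flip noise alone caps even an ideal
founder-recovering predictor near 0.98, and occasional flipped tag calls
cost the rest. The 12-candidate optimality check uses injected class
sizes drawn from 1–8.

What this does *not* show about real data: real LD blocks have ragged
boundaries, allele frequencies far from 0.5, more founder haplotypes
with unequal frequencies, and LD that decays with distance rather than
dropping to noise at a block edge. On such data the λ-cut will produce
many singleton classes, `|SI|` grows, and the swarm's search actually
matters; accuracy ceilings are set by recombination history, not by an
injected flip rate. The simulator validates the machinery, not the
field performance.

## Numerical and design notes

* λ defaults to 0.8, the conventional strong-LD threshold; the right
  value is data-dependent and `ld_cluster()` exposes it. If
  `n_tags > |SI|`, the selector refuses and suggests lowering λ (which
  merges fewer classes and yields more candidates).
* All randomness — swarm initialization, velocity and position draws,
  simulation — flows from a single seed argument; identical seeds give
  byte-identical command outputs. The run record JSON deliberately omits
  wall-clock time (kept in the in-memory object) so that reruns are
  byte-comparable.
* The plain-text matrix writer emits `#samples:` / `#loci:` comment
  headers so ids survive a round trip; readers of the bare format ignore
  comment lines.
* VCF input takes phased, biallelic sites only; unphased or multiallelic
  sites are skipped with a count. Major/minor recoding ties (exactly
  equal allele frequencies) go to the REF allele, for determinism.
* Problem sizes in the test and acceptance runs (matrices up to 50×10
  for the LD oracle, 6×6 relations for the closure oracle, 20 LOOCV
  replicates of 200×20) were chosen so the full suite completes in a few
  minutes while still exercising every contract at non-trivial size.

## A short tour

```{r example, eval = FALSE}
sim <- simulate_haplotypes(n_haplotypes = 200, mutation_rate = 0.02,
                           seed = 9)
clus <- ld_cluster(sim$haplotypes, lambda = 0.8)
glance(clus)                 # classes found
autoplot(clus)               # LD heatmap, loci ordered by class

sel <- bpso_select(clus, n_tags = 4, seed = 9)
autoplot(sel)                # incumbent fitness trajectory

acc <- loocv_accuracy(sim$haplotypes, sel$tags)
glance(acc)
autoplot(acc)                # per-fold accuracy histogram
```
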