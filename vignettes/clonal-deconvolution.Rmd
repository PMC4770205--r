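---
title: "Clonal deconvolution from copy ratios and B-allele frequencies"
author: "clonecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal deconvolution from copy ratios and B-allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecall)
```

## The model

A bulk tumor biopsy is a mixture of normal diploid cells and one or
more tumor cell populations.  `clonecall` treats the tumor genome as a
chain of homogeneous segments and describes each segment by a triple
$(x, y, p)$: the integer copy numbers of the two parental alleles
(labelled so that $x \le y$; allele B is the more abundant one) and the
*prevalence* $p$ — the fraction of all cells in the biopsy carrying
that state.  Mixed with the diploid background, a segment has expected
total copy number

$$\overline{CN} = 2(1 - p) + (x + y)\,p,$$

an expected copy ratio relative to the matched normal

$$R = \overline{CN}/2 = (1 - p) + \tfrac{x + y}{2}\,p,$$

and an expected B-allele frequency at heterozygous germline loci

$$\mathrm{BAF} = \frac{y\,p + (1 - p)}{(x + y)\,p + 2(1 - p)},$$

from which the phase-free *heterozygous-deviation score* follows:

$$\mathrm{HDS} = |\mathrm{BAF} - 0.5|
  = \frac{p\,|y - x|}{2\,[(x + y)\,p + 2(1 - p)]}.$$

Each genotype $(x, y)$ traces a *branch* in the $(R, \mathrm{HDS})$
plane as $p$ runs from 0 to 1; all branches emanate from the normal
point $(1, 0)$.  A segment observed at its median copy ratio and median
HDS — a *bubble*, drawn with area proportional to its genomic length —
falls on the branch of its true genotype at the tick of its true
prevalence.  Reading the plane therefore solves the deconvolution: the
segments of highest prevalence mark the dominant clone (the purity),
distinctly lower prevalences mark subclones, and every segment gets an
allele-specific copy number.  For example, a one-copy loss $(0, 1)$
present in 75% of cells sits at $R = 0.625$, $\mathrm{HDS} = 0.3$.

The raw ratio $R'$ produced by depth comparison is normalized to each
sample's genome average, so a tumor of average ploidy $\tau_t \ne 2$
compresses or stretches the axis.  The correction is multiplicative:

$$\Phi = \frac{\tau_t\,p + 2(1 - p)}{2}, \qquad R = R'\,\Phi .$$

## From raw inputs to bubbles

`select_het_loci()` keeps loci that are heterozygous in the normal
sample (allele fraction within `baf_window`, default 0.4–0.6, at
`min_normal_depth` ≥ 10) and adequately covered in the tumor
(`min_depth`, default 15 reads).  `homogenize()` attaches the loci to
the copy-ratio segments (1-based inclusive coordinates, the native
convention of CBS-style segment tables; BED input is shifted on read)
and summarizes each segment.

Two HDS summaries are kept deliberately:

* `hds_median` — the median per-locus folded BAF.  This is the
  conventional score and is what reports display, but the folded median
  of binomial noise has a sampling floor of about
  $0.674\sqrt{0.25/d}$ at depth $d$ (~0.06 at 34×), so balanced
  segments never read exactly zero.
* `hds_fit` — the maximum-likelihood deviation under a symmetric
  binomial mixture (each locus draws its alt count from
  $\mathrm{Bin}(d, 0.5 \pm h)$ with equal probability, reflecting
  unknown phase).  This estimator is what the caller fits against.  It
  is essentially unbiased away from zero but still has an
  $O(n^{-1/4})$ floor near $h = 0$ (the mixture is weakly identified
  there), so the engine shrinks estimates below a per-segment
  threshold $\max(0.02,\; 2.5\sqrt{0.25/d}\,/\,n^{1/4})$ — tracking
  that floor through the locus count $n$ and depth $d$ — to exactly
  zero (the median path uses 0.02 plus its own depth floor).  Below
  the threshold, "balanced" and "slightly unbalanced" are empirically
  indistinguishable, and leaving the floor in place lets
  low-prevalence branches absorb disomic segments.  The likelihood
  is maximized by a coarse grid scan followed by local refinement; a
  blind golden-section search fails at high depth where the likelihood
  is a needle.

Segments are discarded as *inhomogeneous* when the standard deviation
of per-locus HDS exceeds `sd_cutoff = 0.2`, or when fewer than
`min_het = 10` informative loci support them; exclusions are reported
with reason codes, never silently dropped.

## The three-step caller

**Step 1 — scale.** `fit_ploidy()` profiles $\Phi$ continuously over
0.6–2.6 (step 0.005, refined locally afterwards) rather than assuming
an integer ploidy: a deletion-heavy "diploid" tumor has
$\tau_t \approx 1.9$ and a genuinely non-unit $\Phi$.  At each scale
the large segments (≥ `large_threshold_bp`, default 5 Mb) are matched
to their nearest branch point, with distances measured in the **raw**
observable space (the lattice mapped through $1/\Phi$) so that the same
measurement noise costs every candidate scale equally.  A scale is
admissible only if it is self-consistent: the tumor ploidy implied by
its own assignments (the length-weighted mean assigned total copy over
the clonal mass) must reproduce $\Phi$ through the displayed formula.
Admissible scales are grouped into integer ploidy classes (2, 3, 4 by
default; monoploid and ≥ pentaploid genomes are not searched).

Classes are then compared on the **constrained** residual: prevalences
are detected (step 2) and every large segment is re-assigned under the
shared prevalence set (step 3), because the unconstrained
nearest-branch score is not comparable across classes — the dense
high-copy lattice of a polyploid reading can quantize pure measurement
noise.  Two further parsimony rules guard the comparison: a class may
only invoke states up to $x + y = \mathrm{class} + 2$ while classes
compete (the full lattice, up to decasomy by default, is used for the
final assignment), and near-ties resolve as follows.  A genome doubled
at purity $p$ is *exactly* indistinguishable from a diploid genome at
$p' = p/(1+p)$ (the state $(x{+}1, y{+}1)$ at $p$ reproduces the raw
scores of $(x, y)$ at $p'$, to machine precision).  When a tied pair of
classes exhibits that twin signature, the high-purity (polyploid)
reading is returned as primary — the package assumes biopsies are
enriched for tumor — and the diploid twin is kept in `alternative`;
`prefer_high_purity = FALSE` flips this.  Ties without the twin
signature resolve to the lower class.

**Step 2 — prevalences.** `detect_prevalences()` matches each large,
ploidy-adjusted, non-disomic segment to the branch lattice with
prevalence on a 0.005 grid spanning
$[\texttt{min\_prevalence}, 1]$ (default floor 0.1 — below that every
branch crowds into the normal point and matches are meaningless), then
clusters the matched prevalences by average-linkage hierarchical
clustering cut at `cluster_cutoff = 0.2` and reports cluster medians,
descending; the largest is the purity.  Two kinds of segments carry
weak evidence and may *corroborate but not seed* a cluster:

* segments whose two nearest branches are nearly equidistant (within
  `ambiguity_frac = 10%`) — the branch pairs ABB at $2p$ and ABBB at
  $p$ are *identical curves*, so such matches cannot pin $p$;
* balanced segments, because the whole family $(k, k, p)$ coincides
  with $(k', k', p\,(k-1)/(k'-1))$ exactly.

A weak segment seeds a cluster only when *every* near-tied
interpretation of it is isolated from the existing evidence; this is
how a subclone marked by a single ambiguous gain still surfaces while
coincidence artifacts do not.  Cluster medians closer than the cutoff
are merged, so reported prevalences are always separated by at least
`cluster_cutoff`.

**Step 3 — assignment.** `assign_ascn()` restricts the lattice to the
detected prevalence set plus the disomy state AB and gives every
segment its nearest state; ties break to the smaller total copy
number, then the larger prevalence, making output deterministic.  The
length-weighted mean distance is reported as `fit_residual`.
`brute_force_fit()` — an exhaustive per-segment search over the dense
lattice, refusing instances above 12 segments — exists purely as an
independent oracle for the test suite.

## Somatic-variant chronology

Given fitted states, a somatic mutation on $m$ copies in a fraction
$p_m$ of cells has expected allele frequency
$m\,p_m / [(x+y)p + 2(1-p)]$.  The four canonical scenarios are
instantiations of $(m, p_m)$: on allele B before the SCNA ($m = y$),
on allele A before it ($m = x$), after it ($m = 1$), or unique to a
subclone ($p_m$ = that subclone's prevalence, with $m = 1$ or $y$).
Scenarios with no mutant copy are dropped and coinciding bands collapse
— on a disomic segment everything clonal reduces to $p/2$.
`classify_variants()` labels each observed variant with the nearest
band of its host segment when the residual fits within a fixed margin
(`tolerance = 0.05`) plus the binomial 95% half-width at the variant's
depth, and otherwise reports `unexplained`; variants outside fitted
segments are `unassigned`, never guessed.  Disomic segments use the
callset purity as their clonal prevalence (their lattice prevalence is
a placeholder).

## The simulator

`simulate_segments()` generates the sufficient statistics the caller
consumes — per-segment ratios and per-locus allele counts — directly
from a clone-tree mixture; read-level simulation would add cost without
adding information the model sees.  Cell fractions are proportional to
per-haploid coverage (a cell of ploidy $\tau$ yields $\tau$-fold
reads), the mixture ratio generalizes the two-component model to
$R' = \sum_c f_c n_c / \sum_c f_c \bar\tau_c$ over all components, and
BAF analogously; children inherit ancestral SCNAs unless they override
them.  Noise: segment ratios get
$\mathcal N(R', \mathrm{sd\_r}/\sqrt{n_\mathrm{markers}})$
(`sd_r = 0.25` per 50 kb marker), locus depths are Poisson around the
local expected coverage, alt counts binomial with random phase, and
the matched normal is drawn at 30×.  `noise_free = TRUE` replaces
draws with exact expectations.

Fifteen ready-made designs (`sam_config("sam1")` … `"sam15"`) mirror a
standard benchmark layout: a normal-only control, a pure diploid tumor,
a purity ladder, nested subclones (T1 → T1a/T1b), an independent
second clone (T2), a triploid (T3) and a tetraploid (T4) clone.  The
default het density is 1 per 60 kb (~50k loci genome-wide); the caller
uses per-segment summaries, so density beyond a few hundred loci per
segment adds runtime, not information.  The T4 clone deliberately
carries only states that have diploid twins, so the tetraploid design
exhibits the doubling degeneracy in full and is resolved by the
high-purity preference; the triploid design carries a deep loss that
makes it identifiable outright.

What the simulator does *not* emulate: GC and mappability waves in the
ratio track, segmentation errors (breakpoints are exact), mismapped or
contaminated loci, and replication-timing artifacts.  Passing tests on
simulated data therefore demonstrate correctness of the inference
given well-formed segment summaries, not robustness to upstream
artifacts.

## Degeneracies and limitations

* Purity below ~0.5 with only twin-compatible states is genuinely
  unidentifiable against a doubled genome; the callset then carries
  both readings (primary + `alternative`).  Two independent clones at
  equal prevalence are reported as one (their shared prevalence is the
  only identifiable quantity).
* Prevalences closer than `cluster_cutoff` merge by design; lowering
  the cutoff splits them at no extra cost but admits more noise
  clusters.
* Subclonal balanced states are invisible; segments whose subclones
  carry different SCNAs over the same span land between branches and
  are assigned to the nearest integer state.
* A normal-only genome raises "no informative SCNA" rather than
  reporting an arbitrary purity.

## Problem sizes and determinism

The shipped analyses run on a 22-autosome, ~3 Gb genome with ~30
segments and ~50k loci (the pipeline acceptance rerun), ~10–35k loci
in unit tests, and 100 twelve-segment noise-free instances for the
oracle-equivalence property; one full pipeline run takes a few seconds
on one core.  The engine itself is deterministic — only the simulator
consumes random numbers, always through an explicit seed.
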