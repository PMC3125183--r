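---
title: "Predicting CpG islands with a complementary particle swarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CpG islands with a complementary particle swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgswarm)
library(dplyr)
```

## The problem

CpG islands are genomic segments with unusually high G+C content and an
unusually high frequency of the CpG dinucleotide relative to what the base
composition alone would predict. They mark promoters and transcription start
sites and are largely unmethylated, which makes finding them a standard step
in annotating regulatory regions. The classical rule sets are threshold
definitions over three statistics of a candidate segment of length $N$ (with
$N$ counting only called bases; `N` residues are excluded and also break
dinucleotides):

* GC content: $\mathrm{GC} = (n_C + n_G) / N$,
* CpG observed/expected ratio:
  $\mathrm{O/E} = n_{CpG} \cdot N / (n_C \cdot n_G)$, defined as 0 when the
  segment has no C or no G,
* segment length.

The GGF (Gardiner-Garden/Frommer) criteria require length $\ge 200$ bp,
$\mathrm{GC} \ge 0.50$ and $\mathrm{O/E} \ge 0.60$; the stricter Takai-Jones
(TJ) criteria (length $\ge 500$, $\mathrm{GC} \ge 0.55$,
$\mathrm{O/E} \ge 0.65$) are conventional when Alu repeats have been masked,
because some Alu copies mimic island composition. All boundaries are
inclusive. `cpgswarm` takes repeat annotations as BED intervals and masks
them to `N`; it does not detect repeats itself.

Most classical tools scan a fixed-width sliding window, which ties the
result to the window-width choice. The approach implemented here instead
treats island finding as an optimisation problem: a candidate island is a
point $(F_s, F_l)$ — start offset and length inside a window of sequence —
and a particle swarm searches that two-dimensional space directly, so
island boundaries are not quantised by a scan width. (The classical scanner
is still included, as `sliding_window_baseline()`, because it is a useful
independent comparator in tests.)

## The optimiser

Each of 300 particles carries a position $x = (F_s, F_l)$, a velocity, and
its personal best $pbest$; the swarm tracks the global best $gbest$. Per
iteration, with $r_1, r_2 \sim U(0,1)$ drawn fresh per particle and
dimension:

$$v^{new} = w\,v^{old} + c_1 r_1 (pbest - x) + c_2 r_2 (gbest - x), \qquad
x^{new} = x^{old} + v^{new},$$

with $c_1 = c_2 = 2$ and the inertia weight annealed linearly,
$w = w_{max} - (w_{max} - w_{min})\, i / i_{max}$, from 0.9 to 0.4 over 100
iterations. Velocities are clipped to $\pm v_{max}$ per dimension; we
default $v_{max}$ to one fifth of the window length, since unbounded
velocities diverge on bp-scale coordinates. Positions stay real-valued
between iterations and are rounded to integer bp (and clamped into the
window, lengths into the 200–2000 bp band) at fitness evaluation; boundary
repair is by clamping rather than reflection, the simplest contract for
tests to rely on. The end coordinate is derived, $F_e = F_s + F_l$, which
keeps the length constraint enforceable by clamping a single dimension.

The fitness of a candidate with statistics $(\mathrm{GC}, \mathrm{O/E}, l)$
is

$$f = \begin{cases}
\mathrm{GC} + \mathrm{O/E} + \ell(l) & \text{if all three criteria hold} \\
0.1 \times (\#\text{criteria satisfied}) & \text{otherwise,}
\end{cases}$$

where $\ell(l)$ rescales length linearly onto $[0,1]$ between 200 and
2000 bp. The feasible floor ($0.5 + 0.6 + 0 = 1.1$) strictly dominates the
infeasible ceiling ($3 \times 0.1 = 0.3$), so whenever any feasible segment
exists the argmax satisfies the criteria, while infeasible candidates still
carry a coarse gradient toward feasibility. All-`N` candidates score 0. The
additive form, the gating, and the 0.1 penalty scale are this package's
design choices for composing the three component scores; the exhaustive
oracle below maximises exactly the same function, so tests compare the
optimiser against the true optimum of the objective actually used.

### Stagnation and the complementary restart

A swarm attracted to a local optimum stops improving: when $gbest$ is
bit-identical for 5 consecutive iterations (fitness is exactly reproducible
because evaluation happens at integer bp), half the particles — chosen
uniformly at random, never the particle holding $gbest$ — are repositioned
to their opposition point

$$x^{complement} = X_{max} + X_{min} - x,$$

componentwise over the search box, with velocity reset to zero and personal
bests retained. The mapping is an involution of the box onto itself, so
repeated restarts cannot drift out of bounds. Because the restarted
particles keep feeling the original $gbest$, the swarm either confirms the
incumbent or finds the better basin; replacing half balances exploration
against not destroying the converged half. Equality of fitness (not of
position) defines "unchanged", since positions can drift at equal fitness.
Plain PSO is available as `mode = "pso"` for comparison.

### Windows, deflation and merging

Chromosome-scale sequences are tiled into 10 kb windows overlapping by
2 kb. The overlap exceeds the 2000 bp maximum candidate length, so an
island crossing a window seam lies wholly inside the neighbouring window.
One swarm runs per window; when it returns a feasible island, the island's
span is masked to `N` and the window is rerun (deflation) up to 5 more
times, which is how multiple islands per window are recovered. The mask is
shared across windows, so a seam island is not found twice; any remaining
strictly-overlapping finds are unioned, and all statistics are restated on
the original, unmasked sequence. The window size itself is a free
parameter; 10 kb keeps each swarm's search box small relative to the
velocity bound while amortising profile construction.

After extraction, a merge pass scans the sorted islands left to right: any
adjacent pair separated by less than 200 bp is tentatively merged into the
spanning interval, and the merge is kept only if the span itself still
satisfies the active criteria — an accept-if-rewarded rule. An accepted
span immediately tries to absorb the next island; the pass repeats until a
full pass changes nothing. The fixed point is idempotent, never has more
islands than the input, and never covers fewer bases (accepted merges
absorb gap bases). No learned value function, learning rate or discount
appears because the rule is fully determined by the criteria; likewise,
islands are not extended outward without a neighbour — only merge-driven
extension is implemented, since no outward-extension rule is specifiable
from the criteria alone. "Distance" is the end-to-start gap, the only
reading commensurate with the 200 bp minimum island length.

## Evaluation

Evaluation is per nucleotide. Against a reference annotation, every base is
TP (in both), FP (predicted only), FN (reference only) or TN (neither), and

$$SN = \frac{TP}{TP+FN},\quad SP = \frac{TN}{TN+FP},\quad
ACC = \frac{TP+TN}{TP+FP+TN+FN},\quad PC = \frac{TP}{TP+FN+FP},$$
$$CC = \frac{TP \cdot TN - FN \cdot FP}
{\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}.$$

Counts are computed by interval arithmetic and checked in the test suite
against an explicit per-base bitmap oracle; a metric with a zero
denominator is reported as `NA` rather than raising. ROC points are
produced by sweeping a threshold over island fitness (the package's
choice of score; any monotone score would do) and always shrink in both
coordinates as the threshold rises.

Report summaries follow genome-annotation conventions: coverage is
$100 \times$ total island length / sequence length (displayed to one
decimal), methylation density is sites-inside-islands per island bp as a
percentage (two decimals), per-island GC and O/E summaries use population
standard deviations, and promoters are $[\mathrm{TSS}-1500,
\mathrm{TSS}+500)$ bp, mirrored on the minus strand. TSS/promoter overlap
counts TSSs (a TSS-centric convention: one count per site, regardless of
how many islands it touches). Internally all values are kept at full
precision; rounding is display-only.

## The synthetic benchmark

Real chromosome-scale benchmarks require reference annotations that cannot
be bundled, so the package ships a generator whose fixtures carry exact
ground truth. The background is a first-order Markov chain: all transition
rows equal the target base distribution except the C row, where
$P(G \mid C)$ is multiplied by a suppression factor and the row
renormalised. This makes the realised O/E track the suppression factor
directly, which is the one background property the method is sensitive to.
Islands are generated from the same chain (suppression set to the target
O/E), rejection-sampled until empirical GC and O/E are within 0.03 of
target, and spliced in at positions respecting a minimum gap, so the truth
BED is correct by construction and always GGF-feasible.

The canonical fixture is a 100 kb background at GC 0.41 with suppression
0.25 — mammalian-like CpG depletion — carrying eight islands spanning
lengths 300–1800 bp, GC 0.55–0.65 and O/E 0.70–0.90, separated by at least
2 kb. At these sizes ten seeded end-to-end replicates run in well under a
minute, and the exhaustive oracle stays tractable on sub-windows. What the
generator does *not* emulate: isochore structure, repeats (no Alu mimicry
— masked-mode tests use synthetic mask intervals), assembly gaps beyond
what `N`-handling tests construct, and the clustered, TSS-associated
placement of real islands. Passing the benchmark therefore demonstrates
that the optimiser and refinement recover composition-defined islands
against a depleted background; it does not certify performance on real
chromatin, where island/background contrast is messier.

Two auxiliary fixtures exercise specific mechanisms. The escape fixture
puts a weak 400 bp island and a much better 1500 bp island in one 6 kb
window and confines the initial swarm near the weak one; the complementary
restart reflects trapped particles to the far side of the box, where the
better island lies. The merge fixture uses an island pair whose combined
span (3700 bp) exceeds the 2000 bp candidate cap, separated by a CpG-free
G/C gap: absorbing that gap piecemeal lowers O/E faster than the length
score rises, so single candidates stop at the island edges, and only the
merge pass — which evaluates the whole span — joins the pair. On generic
fixtures the length-rewarding fitness lets extraction absorb small gaps
itself, and refinement changes nothing; this is the expected behaviour,
not a defect.

## Numerical choices and degenerate inputs

* O/E is 0 (not `NA`) when a segment has no C or no G; all-`N` segments
  give `NA` statistics and fitness 0.
* Exact fitness equality defines stagnation; ties in the exhaustive oracle
  break toward smaller start, then smaller length, making it
  deterministic.
* Windows shorter than 200 bp are skipped with a message; a genome shorter
  than the window size is processed as a single window.
* All randomness flows through R's RNG; `cpg_predict()` seeds it from
  `config$seed`, so identical configurations reproduce identical island
  lists bit for bit.
* `read_fasta()` uppercases and maps every non-`ACGT` character to `N`;
  coordinates are 0-based half-open everywhere in memory and on disk
  (BED), with 1-based display only in printed reports.

## Known limitations

* The optimiser maximises a composition score, so predicted boundaries
  overshoot into flanking sequence until a criterion binds; against sharp
  planted truth this costs precision (visible as CC < SN in the
  benchmark). Real island boundaries are themselves fuzzy, but users
  needing CpG-anchored edges should trim separately.
* One swarm per window, sequential; no parallel or multi-swarm variants.
* Deflation recovers up to `restarts_per_window + 1` islands per window;
  unusually island-dense windows need that raised.
* The probabilistic island models of the CpGProD/CpGcluster family are a
  different method family and out of scope.
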