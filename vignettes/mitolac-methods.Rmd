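---
title: "Profiling mtDNA mutation load with CGR lacunarity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling mtDNA mutation load with CGR lacunarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitolac)
```

## The problem and the model

Mitochondrial DNA is present in thousands of copies per cell and mutates an
order of magnitude faster than the nuclear genome. A resequencing array or
caller reports a subject's mtDNA as a single IUPAC string: a determinate
base where one allele dominates, a two- or three-fold ambiguity code where
two alleles coexist (heteroplasmy), and `n` where quality was insufficient
(no-call). Comparing with a reference yields three per-subject burdens —
homoplasmic substitutions, heteroplasmic sites, no-calls — but burdens alone
ignore *where* the deviations fall. `mitolac` instead treats the mutated
sequence as a texture and measures how mutations perturb its self-similar
structure.

**CGR.** The Chaos Game Representation of a sequence at word length $L$ is
the $2^L \times 2^L$ matrix $A$ whose cell $p(s)$ counts the occurrences of
the $L$-mer $s$ among all overlapping windows (unit step, no circular
wrap-around, so the total mass is exactly $|S| - L + 1$). The cell map comes
from the $L$-fold tensor power of a $2\times2$ generator that assigns each
base one row bit and one column bit; the default corner layout is
$c \to (0,0)$, $g \to (0,1)$, $a \to (1,0)$, $t \to (1,1)$, with the *first*
symbol of the window selecting the coarsest quadrant. Human mtDNA produces
the well-known Sierpinski-like CGR image, and mutations perturb it locally.

**Undetermined symbols.** A window containing ambiguity codes stands for $N$
determinate $L$-mers ($N$ = product of the symbol multiplicities); each is
deposited with weight $w = 1/N$, so every window contributes total mass 1
regardless of its ambiguity. `expand_substring("tamcg")` gives `taacg`,
`taccg` at $w = 1/2$; `expand_substring("tavcgm")` gives six strings at
$w = 1/6$. On a determinate sequence the weighted builder reduces *exactly*
to plain counting (this is asserted as a test invariant). Windows containing
`n` are expanded as four-fold undetermined symbols by default; because a
subject can carry on the order of $10^3$ no-calls and nothing in the calling
pipeline distinguishes "either allele" from "unknown" at deposit time, we
treat both uniformly, and `cgr_config(n_policy = "drop")` provides the
alternative of skipping such windows entirely (mass conservation then
excludes them).

**Sigmoid regularization.** Before texture analysis each entry $I$ is mapped
to $J = 1/(1 + e^{-k(I-\sigma)})$. The defaults $k = 7$, $\sigma = 0.7$ place
the threshold *between* fractional heteroplasmic deposits ($\le 1/2$) and
integer counts ($\ge 1$): a cell whose mass comes only from split windows is
pushed toward 0 (a "gap"), an ordinary cell toward 1. This is why the
transform is applied to the **raw** weighted counts; a `normalize = TRUE`
mode (divide by the maximum first) is provided for sensitivity analysis but
changes the meaning of $\sigma$ and is off by default.

**Gliding-box lacunarity.** For each integer box size $b \in [b_{\min},
b_{\max}]$ a $b\times b$ window glides over the image one unit at a time
(interior positions only), giving $N(b) = (2^L - b + 1)^2$ box masses $M$.
With raw moments $Z_q = \frac{1}{N(b)}\sum_j M_j^q\, n(M_j, b)$, the
lacunarity is

$$\Lambda(b) = \frac{Z_2}{Z_1^2} \ \ge\ 1,$$

with equality exactly when all box masses coincide (uniform image, or the
single whole-matrix box at $b = 2^L$). A scale with zero total mass leaves
$\Lambda$ undefined; the point is recorded as missing and skipped by the
fit. Moments are computed over all boxes via a summed-area table; the
distinct-mass frequency formulation is kept for reporting and the two are
asserted equal in tests.

**Hyperbola model.** The curve is summarized by

$$L(b;\alpha,\beta,\gamma) = \frac{\beta}{b^{\alpha}} + \gamma,
\qquad \alpha,\beta,\gamma > 0,$$

fitted by least squares. $\alpha$ is related to the fractal dimension of the
image, $\gamma$ is the large-$b$ asymptote (near 1), and $\beta$ — the
amplitude of the lacunarity decay — is the biomarker: it condenses the
number, type and placement of mutations into one number per subject.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `L` | 5 | letters (1–12) | 32×32 matrix; mean cell mass ≈ 16 for a whole genome, ≈ 4 for the np 5713–9713 frame; `L = 6` is the documented alternate |
| `k` | 7 | — | sigmoid steepness; larger values binarize harder |
| `sigma` | 0.7 | mass units | separates fractional (≤ 0.5) from whole (≥ 1) deposits |
| `b_min` | 3 | cells | smallest gliding box; 5 is the documented alternate |
| `b_max` | order/2 (16 at L = 5) | cells | keeps ≥ (order/2 + 1)² boxes per scale for stable moments; see "open conventions" |
| `frame` | none | np, 1-based inclusive | e.g. `c(5713, 9713)`, the 4001-np respiratory-chain frame (COI–COIII, ATPase6) |
| `rel_sse_max` | 0.2 | fraction | non-hyperbola-like threshold on SSE / total curve variance |
| `fence_multiplier` | 1.5 | IQR units | Tukey fence for "abnormally high" α exclusion |
| `tail`, `direction` | one, greater | — | the biomarker hypothesis is directional; both configurable |

## Numerical choices

* **Weights.** Per-window deposits are the exact rationals $1/N$
  ($N \le 4^L$) accumulated in double precision; total mass matches
  $|S|-L+1$ to well below the 1e-9 tolerance asserted in tests.
* **Optimizer.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`, lower
  bounds $10^{-12}$), multi-started over $\alpha_0 \in \{0.5, 1, 1.5, 2\}$
  with anchors $\gamma_0 = \min\Lambda - \varepsilon$ and $\beta_0 =
  (\Lambda(b_{\min}) - \gamma_0)\, b_{\min}^{\alpha_0}$; step/objective
  tolerances $10^{-12}$, at most 5000 evaluations. The objective is mildly
  non-convex in $\alpha$; the lowest-SSE start wins. The fit is invariant to
  the order of curve points.
* **Non-hyperbolic verdict.** A curve is rejected when the fit failed to
  converge, when relative SSE exceeds `rel_sse_max`, when the fitted
  amplitude $\beta(b_{\min}^{-\alpha} - b_{\max}^{-\alpha})$ is below
  $10^{-8}$ (flat or rising curves collapse to this degenerate limit), or
  when the curve has no variance at all.
* **Degenerate comparisons.** If every biomarker value in both groups is
  identical the test statistic is 0 and the p-value is the null value (0.5
  one-tailed, 1 two-tailed) rather than an error; a zero pooled IQR declares
  no α outliers. Normality routing uses Shapiro–Wilk at 0.05 per group
  (Student's t with pooled variance when both pass, Mann–Whitney with normal
  approximation otherwise); the routing can be forced with `test =`.
* **Corner conventions.** Lacunarity is invariant under the eight corner
  relabelings that correspond to symmetries of the square (complementing the
  row or column bit of every base, and swapping the two bits — i.e. matrix
  reflections and transposition). It is **not** invariant under the other
  sixteen relabelings (e.g. swapping only the $g$ and $t$ corners induces a
  shear-like cell permutation that changes gliding-box masses), nor under
  the `symbol_order` choice. The default layout is therefore a genuine
  convention, fixed as stated above.

## Open conventions and the reference calibration

The published coefficient set pins $L$, $k$, $\sigma$ and $b_{\min}$ but
leaves three conventions implicit: $b_{\max}$, which end of the window is
the coarsest quadrant (`symbol_order`), and whether counts are rescaled
before the sigmoid. `calibrate_cgr_convention()` runs the pipeline over a
grid ($b_{\max} \in 8..32$ × first/last × normalize on/off) against target
$(\alpha, \beta)$ pairs for the whole sequence and a frame, reporting
relative deviations, so that a user with the true human mitochondrial
reference (GenBank NC_012920 — not redistributed with this package) can
identify and freeze the matching convention. The package defaults
(`symbol_order = "first"`, $b_{\max}$ = order/2, normalize off) are the
stated conventions, not a calibrated choice; the two reference-regression
tests in the acceptance suite remain red until that FASTA is supplied at
`inst/extdata/NC_012920.fasta`.

## What the synthetic generator emulates — and what it does not

`synthetic_cohort()` draws one shared reference with the human mtDNA base
composition (fractions 0.309/0.313/0.131/0.247 of a/c/g/t), then gives each
subject homoplasmic substitutions, two-fold heteroplasmic codes containing
the reference base (the mixed ref/alt call a diploid-mode array emits;
three-fold codes via `hetero_fold = 3`), and `n` no-calls, at burdens drawn
from per-group truncated normals. The default burdens are the case/control
profile of elderly-subject mtDNA resequencing: homoplasmy 18 ± 8 vs 21 ± 8,
heteroplasmy 12 ± 13 vs 10 ± 6, no-calls 1009 ± 765 vs 980 ± 390. Everything
is deterministic given the spec seed.

Mutations are placed uniformly at random; real mtDNA variation clusters by
gene, context and haplogroup, and real no-calls cluster in
difficult-to-tile regions. An optional hotspot window concentrates burden in
a coordinate frame, which is how tests recreate a region-restricted group
difference, but no finer positional model is attempted. Array intensity
noise, base-calling errors and the unpublished mask of array-tiled positions
(the printed reference tallies cover 16,544 of 16,569 np) are likewise out
of scope. Passing tests therefore demonstrate the *algorithmic* contract —
mass conservation, invariances, parameter recovery, test calibration — not
that the biomarker separates real clinical groups.

### The power-simulation condition

The cohort-level acceptance simulation gives case subjects **120 extra
heteroplasmic sites inside the np 5713–9713 frame** (about 3 % of frame
positions, a ~10-fold increase of frame heteroplasmy density) and matches
the no-call burden across groups at 500 ± 100. Both choices were made once,
on these grounds: the no-call burden is the dominant nuisance source of β
variance (its default spread, SD 765, corresponds to call-rate differences
that a matched design would control by chip quality filtering), and with it
matched, a frame-concentrated heteroplasmy excess of this size is the
smallest round effect that the one-tailed β comparison detects reliably at
n = 15 per group. Extra frame mutations *lower* β (more gaps raise the
curve's tail as well as its head, shrinking the fitted amplitude), so the
directional alternative is "case β below control β". The 20-fold
randomized-split control on the same cohorts stays at chance level, and
null cohorts (no extra burden) are non-significant in most seeds — the
pattern expected of a real region-restricted signal.

## Problem sizes used by the test suite

Unit and property tests run on sequences of 10–4000 np and matrices up to
64×64; the acceptance battery uses 1000 randomized ambiguous sequences for
mass conservation, 100 seeded replicates for noisy parameter recovery, 1000
replicates for the type-I rate, and three seeded 30-subject cohorts (16,569
np genomes, frame analysis) plus four null cohorts for the power and
randomized-split checks. `scripts/acceptance.R` uses the same sizes with
seeds derived from `--seed`.

## Known limitations

* β depends on conventions ($b_{\max}$, corner layout orientation) that can
  only be pinned against the true reference sequence; cross-study
  comparisons must hold them fixed.
* The sigmoid threshold interacts with sequence length through mean cell
  mass: at fixed $\sigma = 0.7$, whole-genome images at $L = 5$ saturate
  (most cells well above threshold) and the biomarker is driven by the
  sparse sub-threshold cells, while short frames operate near threshold.
  Comparing β across different frame lengths is not meaningful.
* One-tailed defaults encode a directional hypothesis; use `tail = "two"`
  for exploratory comparisons.
* No multiple-testing machinery is included (single-biomarker design).
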