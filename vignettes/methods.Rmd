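---
title: "Methods: indices, tests and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indices, tests and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odocon)
```

`odocon` implements a conservation assessment workflow for river insect
assemblages surveyed as adults: diversity and conservation indices per
replicate, land-cover heterogeneity per river, compositional ordination,
and among-river testing. This vignette documents the models, the
parameter choices, the numerical edge cases, and what the synthetic data
generator does and does not establish.

## Data model

Four tables drive everything. The **survey** is long-format
(river, site, event, species, count); counts are whole insects (or
estimated counts for swarming damselflies), and zero-count rows are
rejected unless absences are explicitly enabled, because silent zeros
usually indicate transcription slips. The **sample registry** lists
every (river, site, event) actually surveyed. This is load-bearing:
a sample in which no animal was seen must enter the analysis as a
richness-0, abundance-0 replicate rather than disappear — dropping it
would bias every per-river mean upward. The **trait table** carries
per-species taxonomy, an endemism flag, a semivoltinism flag (more than
one year per generation), a national red-list category (LC/NT/VU/EN/CR,
plus literal `"NA"` = not assessed) and the three 0–3 DBI subscores.
Subscores are expert-assigned inputs — they come from regional atlases,
red lists and expert judgement and cannot be derived from first
principles, so the package treats them strictly as data. The
**land-cover table** holds per-river class compositions (areas or
percentages), the tabular product of a GIS buffer-intersection workflow
that is out of scope here.

Species names are normalized on ingest (whitespace squashed, case-folded,
genus re-capitalized) so trait joins are deterministic; duplicate keys
are errors naming the offending row.

## Land-cover heterogeneity

`HHI = Σ (100·P_j)²` over the k class shares of a river. We store shares
as proportions and scale by 100 inside the formula, making the printed
form literal; tables given in percent are divided by 100 on ingest. The
attainable range is [10000/k, 10000], not [0, 10000]: the lower bound 0
sometimes quoted for this index is unreachable for finite k, and the
tests assert the sharp bound. Merging two classes always adds
2·(100P_i)(100P_j) ≥ 0, so coarser classifications can only look *less*
heterogeneous — worth remembering when comparing studies that used
different class levels. k = 1 is accepted with a warning (returns 10000)
so a degenerate buffer does not crash a batch run; the sum-to-one check
uses tolerance 1e-6 after renormalization.

## Diversity indices

The Rényi profile uses natural logs, with the α = 1 and α = ∞ limits
implemented analytically (Shannon entropy and −ln max p) rather than by
approaching them numerically, which would lose precision near the
removable singularity at α = 1. The default grid
{0, 0.25, 0.5, 1, 2, 4, 8, ∞} spans the named special cases (richness,
Shannon, Simpson, Berger–Parker). An empty assemblage yields an all-`NA`
profile: ln 0 is undefined and reporting 0 would conflate "no animals"
with "one species".

RTD = 1/√(N_family·N_genus·N_species) is computed on presences only.
Because every species adds at least one distinct-species unit, adding a
species from a new family strictly lowers RTD (tested exhaustively on
small assemblages).

Per-river richness is reported **pooled** over all sites and events (the
conventional "species recorded at the river" figure) alongside the
replicate-level values used in testing; both are emitted because the two
are easily confused and differ substantially under patchy occupancy.

## Conservation indices

Per-species DBI is the plain sum of the three subscores; the
standardized DBI of a unit is the mean over species present, bounded in
[0, 9].

The CCOI, `((F+G)/2 · (3E + 3S + R + ΣRTD + ΣRLC)) / N`, combines
taxonomic breadth with conservation weighting. Two accumulation details
are genuinely open in its verbal definition and are resolved here as
configuration with documented defaults:

- **Overlap.** "R = total minus endemic and semivoltine species" does
  not say what happens when one species is both. The default (`set`)
  counts such a species once in E and once in S and sets
  R = N − |E∪S|, so E + S + R = N + |E∩S| and R never goes negative; a
  strict `exclusive` mode errors instead. The double crediting is
  deliberate: a species carrying both traits genuinely carries both
  kinds of conservation signal.
- **Scope of ΣRTD.** "Accumulated relative taxonomic distinctness" is
  interpreted, per replicate, as that replicate's own RTD (default),
  which keeps single-replicate CCOI well-defined and makes the worked
  examples exact: one LC, non-endemic, non-semivoltine species gives
  CCOI = (1·(1+1))/1 = 2. A `river` scope that sums the river's
  replicate RTDs is also implemented; neither is asserted to be "the"
  published convention, and results under the two scopes should not be
  mixed.

Red-list scores default to {LC: 0, NA: 0, NT: 0.5}; threatened
categories have no canonical weight in this scheme, so their presence
without a user-supplied score is an error rather than a guess.

## Ordination

Bray–Curtis percent similarity, `100·(1 − Σ|x−y| / Σ(x+y))`, is computed
on log(x+1)-transformed absolute abundances (natural log; base-10
switchable — the choice changes similarities, so it is fixed in
configuration rather than left implicit). Empty samples have no defined
similarity to anything and are dropped with a notice before the matrix
is built. NMDS minimizes Kruskal stress-1 via monotone regression,
delegated to the `vegan` engine with seeded random restarts (default
50); the contract is stress quality and bit-reproducibility from the
seed, not coordinate equality with any desktop package — NMDS solutions
are only defined up to rotation, reflection and scale anyway. The
cluster overlay uses group-average (UPGMA) linkage — the convention of
the software lineage this workflow comes from; the linkage is an
assumption, not a published fact — and cuts the dendrogram at similarity
thresholds (cut at t ⇔ dissimilarity height 100 − t).

## Among-river tests

Each metric passes a Shapiro–Wilk gate per group, walking the
transformation ladder identity → √x → x^¼ → log(x+1) (log(x+1), not
log x, because replicate metrics legitimately contain zeros). The first
step where every river passes at α routes the metric to one-way ANOVA on
the transformed values with Tukey HSD; otherwise — including any group
with n < 3 or zero variance, where the test is undefined — the fail-safe
route is Kruskal–Wallis. The gate therefore has familywise size of about
k·α under normality, which is conservative in the right direction: doubt
defaults to the nonparametric route.

Kruskal–Wallis uses mid-ranks and the standard tie-correction divisor
`1 − Σ(t³−t)/(N³−N)`; all-tied data return H = 0, p = 1 rather than 0/0.
Post hoc comparisons are Dunn-type z statistics on average ranks with
the tie-corrected shared variance, Bonferroni-adjusted by default
(configurable through `p.adjust`); the exact average-rank procedure of
legacy desktop packages is not published, so Dunn/Bonferroni is stated
as the assumption. Compact letters come from the insertion–absorption
algorithm; non-transitive decision sets are representable (a group may
carry "ab").

## The synthetic world

The generator's defaults emulate the study design this workflow targets:
**4 rivers × 3 sites × 3 events**, a **25-species** regional pool, an
imposed per-river richness gradient of **4/9/14/18**, **one** forced
silent site, near-threatened probability **0.12** (≈3 NT species in 25),
and per-river land-cover compositions over **4/5/8/7** classes. Richness
is imposed by pool subsetting, not emergent, so recovery tests have
exact ground truth; every river-pool species is guaranteed at least one
occurrence, which makes realized pooled richness equal the requested
values by construction. Counts for present species are zero-truncated
negative binomial (mean 5, dispersion 1) — adult odonates at a transect
are clumped, so Poisson would understate replicate variance; occupancy
is an independent 0.6 per sample. Land-cover shares are symmetric
Dirichlet draws with concentration 0.5, which puts expected HHI at
(1.5/(0.5k+1))·10⁴ ≈ 5000 (k=4) down to 3000 (k=8) — the realistic range
for Mediterranean river buffers. One master seed drives fixed substream
offsets (taxonomy +1000, traits +2000, survey +3000, land cover +4000),
so regenerating one table never perturbs another.

What a green test does **not** establish: the generator has no spatial
structure, no phenology, no detection model, and its taxonomy is a
random partition — so tests on synthetic data validate the *algebra and
statistical behaviour* of the pipeline, not ecological realism, and
published field values that depend on unpublished inputs (per-river HHI
from external geodata; CCOI tests needing the full trait table) are
documented as external-data targets rather than asserted.

## Numerical choices, in one place

- HHI sum-to-one tolerance 1e-6; bounds asserted at 1e-9.
- Rényi limits analytic; profile monotonicity asserted at 1e-12 slack.
- Bray–Curtis of two empty vectors: `NA`, never 0 or 100.
- NMDS: best of n seeded restarts; stress is Kruskal stress-1 on the
  0–1 scale.
- Gate ladder steps whose transform is non-finite on the data (e.g. √ of
  a negative value) are skipped as inapplicable.
- Kruskal–Wallis degenerate all-tied case: H = 0, p = 1 by guard.
- ANOVA with zero within-group variance everywhere: error, not Inf.
- SE of a single replicate: `NA`, with the mean still reported.

## Known limitations

No rarefaction or coverage standardization (richness comparisons assume
equal effort, which the replicated design provides); no PERMANOVA; no
mixed models — events are treated as independent replicates, so serial
dependence within a season would inflate the effective sample size; the
CCOI accumulation scope remains a documented convention, not a settled
definition.
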