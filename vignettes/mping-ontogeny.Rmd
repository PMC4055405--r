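---
title: "Modeling mPing transposition through rice ontogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mPing transposition through rice ontogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpingr)
library(dplyr)
```

mpingr studies how the rice MITE *mPing* — a short, non-autonomous class II
transposon that has reached roughly a thousand copies in the active strain
EG4 while staying near fifty copies in ordinary temperate *japonica*
cultivars — amplifies through a narrow developmental window. The package
couples three ingredients:

1. a **cell-lineage model of rice embryogenesis** that says which sampled
   tissues inherit an event placed in a given cell lineage at a given time;
2. a **stochastic cut-and-paste simulator** whose transposition rate is
   gated by the developmental expression of the autonomous partner *Ping*;
3. the **inference pipeline** used on transposon-display data: de novo band
   calling against parents, organ-specificity classification, timing
   inversion, inheritance scoring, and cohort statistics.

Because the corresponding field data are gel images and counts, the package
also ships seeded generators that emulate the three experimental designs
end-to-end, with ground-truth event logs so recovery is measurable exactly.

## The lineage model

Compartments are unitary cell lineages with birth times in days after
pollination (DAP). Double fertilization creates two disjoint products: the
zygote (proembryo) and the triploid endosperm; four pre-fertilization gamete
lineages (egg, the two sperm, the polar nuclei of the central cell) feed
into one product each. The default timeline:

* proembryo 0–3 DAP; SAM and radicle progenitor regionalize at 3 DAP;
* leaf primordia L1/L2/L3 split from the SAM at 5 / 6.5 / 8 DAP. The L2
  time is not independently known; 6.5 is the midpoint of the observed 5
  and 8 DAP initiations and only the order of leaves matters for
  classification;
* L4/L5 are post-germination (defaults 12 / 15 DAP — again only their order
  matters);
* the germline separates from the SAM at the reproductive stage (default
  60 DAP, persisting to 70): rice gametes derive from the SAM, which is why
  embryonic SAM events are heritable;
* endosperm lineage from 0 DAP; gamete lineages from the onset of
  gametogenesis (default −10 DAP).

`tissues_containing(tree, compartment, time)` returns the sampled tissues
(endosperm E, radicle R, leaf blades L1–L5) plus the germline channel GERM
that descend from the event-carrying lineage; an event at exactly a split
time is inherited by the splitting child.

```{r}
tree <- default_lineage()
tissues_containing(tree, "SAM", 4)
tissues_containing(tree, "radicle_progenitor", 4)
```

`candidate_windows()` inverts this map. A band may drop out of an assayed
sample, but can never appear in a tissue outside the event's lineage, so a
placement is *consistent* with an observation when its predicted tissue set
contains the observed set; among consistent placements only those with
minimal predicted sets are reported (the latest cell lineages that still
explain everything observed). When an exact match exists it is the unique
answer. The window table carries each window's full tissue set, so
heritability is simply `GERM %in% tissues`.

```{r}
candidate_windows(tree, c("L1", "L2", "L3", "L4", "L5"))[, 1:3]
candidate_windows(tree, c("R", "L2"))[, 1:3]
```

A pattern spanning the endosperm and the embryo (e.g. `{E, R}`) has no
explaining placement under the default topology: the two subtrees are
disjoint below fertilization, and the shared generative-cell stage is not a
placeable compartment (its events are represented instead by the crossing
rule that both sperm are mitotic copies of one meiotic product).

## The rate model

The transposition rate in compartment $c$ at time $t$ is

$$\lambda(c, t) \;=\; \alpha \cdot m_c \cdot \max\{0,\; \min(E_{\mathrm{ORF1}}(t), E_{\mathrm{ORF2}}(t)) - \theta\}$$

* $E(t)$: the strain's *Ping* expression profile per ORF, in relative units
  (inactive-cultivar ovary at pollination = 1). Both the Myb-like
  DNA-binding protein (ORF1) and the transposase (ORF2) are required for
  *mPing* mobilization, hence the minimum. The C-type default profile is
  piecewise linear with a unique peak (level 8) at 3 DAP; the T-type
  default dips through early embryogenesis and never exceeds threshold.
  *Pong* is treated as transcriptionally silent (its profile contributes
  nothing by default; supplying a profile for it is a one-line change to a
  strain definition).
* $\theta$ (default 1): the expression threshold below which no
  transposition occurs — this is what keeps constitutive basal expression
  from producing events outside the embryogenesis burst, and what makes
  single-copy T-type strains inert.
* $m_c$: per-compartment multipliers. Defaults: 1 for the
  post-regionalization embryo compartments (SAM, radicle progenitor, leaf
  primordia — with no shoot/radicle asymmetry), 0.03 for the proembryo,
  0.01 for the endosperm lineage and 0.002 for the gamete lineages. These
  express that *Ping* transcripts accumulate overwhelmingly in the embryo
  proper around 3 DAP, and they reproduce the observed rarity of
  endosperm-specific and radicle/shoot-specific insertions relative to
  shoot- and radicle-specific ones.
* $\alpha$ (events per compartment-day per unit excess expression): not
  identifiable from published data as an absolute rate; by default it is
  calibrated by `calibrate_alpha()` so that the expected de novo insertion
  load visible in a leaf sample is 15.5 per plant, the load reported for
  selfed progenies of the active strain. With the default profile this
  gives $\alpha \approx 1$.

Excisions run at a fixed fraction of the insertion rate (default 0.1 —
excisions were assayed at only 48 marker loci, so their absolute rate is
likewise unidentified), pick an occupied locus, and are restored with
probability `p_repair` (default 0.5; repair from the sister chromatid or
homolog is documented but unquantified). A repaired excision leaves the
copy number unchanged — the net "copy-and-paste" outcome that lets a
cut-and-paste element amplify.

## Simulation mechanics and numerical choices

Events are drawn per compartment from an inhomogeneous Poisson process:
the intensity is integrated by the trapezoid rule on a 0.02-DAP grid, the
event count is Poisson, and event times are sampled from the discretized
intensity. New insertions draw a uniform locus on a 12-chromosome genome
space (collisions redrawn) and a uniform 2-bp flank, which is the quantity
the 16 selective transposon-display primer combinations bin on. Each event
records the tissue set it reaches; per-tissue genotypes are reconstructed
on demand, so a plant object stays small. Everything is a pure function of
(inputs, seed).

Meiosis is linkage-free: heterozygous germline insertions transmit with
probability 1/2. In a cross, the egg and the polar nuclei are mitotic
copies of one megaspore product and the two sperm are mitotic copies of
one generative cell, so the zygote and endosperm share their
presence/absence sets at fertilization; divergence between embryo and
endosperm arises only from post-fertilization (or post-divergence
gamete-lineage) events.

Assay models: transposon display is dosage-blind (presence/absence only)
and has a detection fraction (default 0.1 of cells) below which a mosaic
band is invisible — the published assay treats bands as binary and states
no limit of detection, so this is exposed, not asserted. CAPS digestion
cuts at every occurrence of the recognition site (default `GTAC`, cut
`GT^AC`); relative expression uses the 2^−ΔΔCT rule with amplification
efficiency fixed at 2.

## What the generators emulate — and what they do not

`generate_ontogeny_cohort()` builds the selfing design (S0 → 8 S1 sampled
at E, R, L1–L5 → 12 S2), `generate_reciprocal_f1()` the two reciprocal F1
cohorts of 16, and `generate_ag_panel()` a 93-strain landrace panel
(48 C-type / 14 T-type / 31 no-Ping by default; only the 14 T-type strains
and the A119/A123 *Ping* copy numbers, 6 and 10, are fixed by report —
the remaining composition is a configuration choice). Panel copy numbers
are overdispersed negative-binomial counts whose medians follow the
C-type > T-type ≈ no-Ping ordering; per-strain panel values are not
published, so only the ordering and the significance behaviour are
emulated.

The generators do **not** emulate gel artifacts, PCR failure, band
co-migration, partial digestion, somatic mosaic fractions below 1, or
epigenetic silencing dynamics. Passing recovery tests therefore show that
the inference pipeline is correct *given* clean binary bands from the
assumed lineage — not that it is robust to every failure mode of real
gels. The default per-band dropout probability is 0.

## Statistics

`summarize_cohort()` reports category counts and shares (shares over
categorized calls; nearest-integer percent is the reporting convention),
per-plant mean ± SE, and the first-leaf distribution.
`steel_dwass()` implements the all-pairs nonparametric comparison used for
copy numbers across *Ping* groups: mid-rank two-sample statistics with
tie-corrected variance, with $q = \sqrt{2}\,|z|$ referred to the
studentized range with $k$ groups and infinite degrees of freedom. With
two groups this reduces exactly to the two-sided normal-approximation
Wilcoxon test, which the test suite verifies to 10⁻⁶; a seeded permutation
mode (distribution of the maximal pairwise $q$) is available for small
groups. `compare_reciprocal()` is the plain two-sided rank-sum comparison
of per-plant de novo loads between cross directions.

## Classification rules and edge cases

The organ-specificity classifier follows the published five categories,
with two explicit conventions: leaf presence confined to L4/L5 (or several
of L1–L3 without an upper-leaf confirmation) is *uncategorized*, because
the alternate-phyllotaxy check against upper leaves is impossible there;
and endosperm plus any embryo tissue is a flagged *composite* reported
separately — it is possible only through a shared gamete lineage and was
never observed. Radicle plus any leaf is radicle/shoot-specific regardless
of which leaves. Missing tissue entries are treated as absent for
classification but retained in the matrices.

## Problem sizes used by the test suite

The suite verifies the classifier against an exhaustive rule table (all
2⁷ presence patterns), the lineage inversion against a 0.1-DAP brute-force
grid, Mendelian transmission with 10,000 gametes and 2,000 selfed
genotypes, timing recovery on 1,000 simulated plants with events confined
to the 3–5 DAP SAM/radicle window, and the Steel–Dwass null with 2,000
simulated three-group panels of 31 strains each. Simulated cohorts in
examples use a few hundred baseline loci rather than the full ~1,000 of
the active strain; the locus count only scales the ancestral band matrix,
not the de novo dynamics.

## Known limitations

* Compartments are unitary lineages: within-tissue mosaicism is a single
  fraction per event (default 1), not a cell-population model.
* Absolute rates ($\alpha$, the excision fraction, `p_repair`) are
  calibrated or conventional, not measured; conclusions should rest on the
  gated-window structure, not on these magnitudes.
* The expression profiles are qualitative piecewise-linear shapes anchored
  at the observed peak time, not fitted curves.
* Leaf-specific insertions arising in mature leaf somatic cells cannot be
  excluded by the data; accordingly the timing output reports the full
  candidate window set rather than a point estimate.
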