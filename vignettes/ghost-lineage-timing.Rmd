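---
title: "Ghost lineages and the relative timing of gene transfers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ghost lineages and the relative timing of gene transfers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Branch-length methods date a horizontal gene transfer (HGT) by the
*acquisition stem* of the recipient clade in the gene tree: the branch
running from the node where the recipient clade attaches to its sister
group down to the recipient crown. When two gene families entered the same
recipient stem lineage at different times, the family with the longer
acquisition stem is read as the earlier transfer.

Ghost lineages — donors that are extinct or simply unsampled — corrupt this
reading. When the true donor leaves no sampled descendant, the recipient
clade attaches to the donor's closest *sampled* relative, which diverged
earlier than the transfer happened; the observed stem is inflated. If the
two inflations happen to reverse the observed order of the two stems, the
relative-timing call *shifts*. `ghostshift` simulates this process end to
end and measures how often shifts occur as a function of the extinction
fraction and the taxon sampling fraction.

## The simulation model

**Species trees.** Complete trees are generated by a constant-rate
birth–death process (speciation rate $\lambda$, extinction rate
$\mu = \varepsilon\lambda$), simulated event by event from a single stem
lineage at the origin and halted at the first instant the number of alive
lineages reaches the target $N$. Extinct lineages are retained as dated
extinct tips. Time is rescaled so $\lambda = 1$; the *extinction fraction*
$\varepsilon = \mu/\lambda \in [0,1)$ is the knob of interest (0.0, 0.5 and
0.9 in the headline sweep). Because the quoted extinction settings carry no
units, we interpret them as $\varepsilon$ with $\lambda$ fixed — the
convention of the simulators this style of study uses; an absolute-$\mu$
mode is available through `bd_params(mu = )`.

Two consequences of these choices are worth naming. Halting at the first
hit of $N$ extant lineages (no grandfathering correction) is the simplest
reproducible stopping rule; it mildly biases the most recent internode but
affects all $\varepsilon$ cells identically. Runs that go fully extinct
before reaching $N$ are discarded and redrawn (cap 10,000 per tree), which
conditions the process on survival, exactly as an observed clade is.

**Recipient clade and transfers.** The recipient (the analog of the
eukaryote crown acquiring genes during its stem period) is an independent
birth–death subtree with the same $\lambda$ and $\varepsilon$, 10 extant
tips by default, rescaled so its crown age sits at 0.25 of the species-tree
origin age. Each two-transfer scenario draws two transfer ages uniformly in
the recipient stem interval — from the recipient crown (the LECA analog) up
to 0.75 of the origin age (the FECA analog) — orders them, and picks a
donor branch for each age uniformly among all branches alive at that age in
the complete species tree (ghost donors are therefore sampled in proportion
to their standing diversity, with no self-transfer since the recipient is
not part of the species tree). The fractions 0.25/0.75 place the transfer
window in the interior of the tree, as a stem period bounded away from both
the root and the present; they were fixed before any sweep was run and are
exposed in `sweep_config()`.

The gene tree of a transferred family is the species tree with a new node
of age $\tau$ inserted on the donor branch and the recipient subtree
hanging from it, so in the complete gene tree the acquisition stem is
exactly $\tau$ minus the recipient crown age — a property the test suite
asserts exactly.

**Ghost mechanisms.** Extinction acts implicitly: pruning extinct tips can
remove all of a donor's descendants. Sampling acts explicitly:
`subsample_taxa()` keeps a uniformly random subset of `round(f * n)` extant
taxa (half-up), re-drawn until at least 2 recipient tips (a crown must
exist for a stem to be measured) and 1 donor-side tip survive. Subsampling
is uniform over recipient and donor-side taxa alike by default; a
donor-side-only mode exists because a "sample 1% of taxa" protocol may
plausibly spare the focal recipient clade. Both pruning operations preserve
all pairwise path lengths among retained tips (unifurcations suppressed,
lengths summed).

**The statistic and the call.** For each family, the observed stem is
$s = d - c$ where $d$ is the apparent divergence age (attachment node of
the recipient clade in the observed tree) and $c$ the observed recipient
crown age. The branch-length ratio $r$ divides $s$ by the median branch
length inside the observed recipient clade (stem excluded). Both are
reported; the default ordering criterion is $s$, because the two families
of a pair share one recipient clade, so the denominator of $r$ cancels and
the two criteria provably agree (also asserted in the tests). The pair is
scored *incorrect* when the observed order reverses the true $\tau$ order;
exact ties — possible because both families can attach at the same surviving
node — are scored incorrect, a policy choice that leans against the method
under test rather than for it.

**The analytic shift conditions.** For two ghosts with divergence ages
$d_g$ and transfer ages $\tau_g$, `shift_possible()` states when a shift is
observable: (a) both divergences fall inside the recipient stem period, and
(b, c) the divergence order is the reverse of the transfer order. The
package checks this calculus against a brute-force oracle that builds each
four-taxon gene tree explicitly, drops the ghost, and reads the stems off
the pruned tree, over an exhaustive grid of age orderings.

## The sweep and its measurement path

`run_cell()` simulates `n_trees` species trees, places `n_pairs`
two-transfer scenarios per tree (all sharing the tree's recipient clade),
applies both ghost mechanisms, and pools the percentage of incorrect calls;
`run_sweep()` maps this over the $\varepsilon \times f$ grid with per-run
seeds derived arithmetically from the master seed, so any cell can be
recomputed in isolation and the entire sweep is byte-reproducible.

Internally the sweep does not build each gene tree: grafting at age $\tau$
and pruning to the retained taxa attaches the recipient at $\tau$ when any
retained tip descends from the donor branch, and otherwise at the youngest
common-ancestor age between the donor branch and a retained tip, so the
apparent age can be read directly off the complete species tree
(`apparent_divergence_age()`). The explicit route — `build_gene_tree()`,
prune, `timing_call()` — is implemented too, and the test suite asserts
that the two routes return identical ages and identical calls on random
scenarios; the tolerance note in `evaluate_event_pair()` exists because
summed edge lengths carry $10^{-16}$ noise that must not break exact
structural ties.

## Diagnostics

`normalized_tip_lengths()` divides each extant terminal branch by the mean
of all branch lengths of the *same* tree's extant restriction. Per-tree
normalization (rather than pooling across an ensemble) makes trees of
different heights comparable, which is the point of the statistic; the
choice matters little for the direction of the $\varepsilon$ comparison but
is stated here because either reading is defensible.

`ltt_curve()` returns the exact lineages-through-time step function of the
extant restriction, and `ltt_recent_slope()` the least-squares slope of log
lineage count over the most recent decile of tree height, measured on
*height-normalized* time. The normalization is essential: higher
$\varepsilon$ at fixed $\lambda$ makes trees much taller (net rate
$\lambda - \mu$), so the absolute end slope *decreases* with $\varepsilon$
even while the curve's end upturn — the pull of the present, the quantity of
interest — grows. On relative time the statistic is a pure curve-shape
measure and behaves as the theory predicts (roughly 6, 10, 19 for
$\varepsilon$ = 0, 0.5, 0.9 at 1,000 leaves).

## Scales, numerics, and degenerate inputs

The headline regime is 1,000-leaf species trees, 24 runs per cell, 50 trees
× 4 pairs (= 200 event pairs) per run. With the compiled simulation core
this runs in about a minute per cell, so the acceptance checks and the test
suite both use the full regime. A reduced 100-leaf regime was considered
and rejected for the 1% sampling cell: at 110 extant taxa, `round(0.01 n)`
falls below the 2-recipient + 1-donor constraint floor, the floor binds (3
retained tips), ties inflate several-fold, and the cell no longer measures
the same protocol.

Numerical choices: ages are reconstructed from edge lengths and anchored at
the deepest extant tip, with sub-$10^{-8}$ negatives clamped to zero;
ultrametricity is asserted at $10^{-6}$ absolute tolerance; coincident
transfer-age draws are re-drawn (they are measure-zero but would make the
true order undefined); a recipient crown at or above $\tau$ is an error
(zero-length stems are disallowed); subsample draws violating the
minimum-kept constraints are re-drawn with a 10,000-draw cap, and a tree
whose constraints cannot be met is redrawn and counted, never silently
dropped from denominators.

## What passing tests do and do not show

The generator emulates the study conditions: time-calibrated trees whose
branch lengths are *true* times, transfers placed on known donors at known
ages, and sampling that is uniformly random. Real data differ in ways that
matter: gene trees are reconstructed from sequences (rate variation,
estimation error, rooting error), taxon sampling is strongly clade-biased,
transfer-age priors are not uniform, and real recipient clades are not
independent subtrees. Passing tests therefore show that the *measurement
chain itself* — not sequence-level inference — behaves as claimed: ghosts
only ever deepen apparent divergences, reversals require the analytic
conditions, and the frequency of reversals falls as extinction rises under
1% sampling while staying below 50%. The package makes no claim about the
rate of shifts in any empirical dataset.

## Known limitations

Constant rates (no time-variable or lineage-specific $\lambda,\mu$); no
fossilized-birth–death sampling of extinct tips; one recipient clade per
tree; no replacement transfers, losses, or duplications; stems are measured
on true chronograms, so all conclusions are about the best case for the
branch-length method, not its sequence-level performance.
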