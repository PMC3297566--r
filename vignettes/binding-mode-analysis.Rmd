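---
title: "Binding-mode networks, windowed RMSF and PDZ family statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-mode networks, windowed RMSF and PDZ family statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzmodes)
```

This vignette records how `pdzmodes` defines its statistics, which
parameters matter, and the design decisions taken where more than one
defensible choice existed. It states no empirical result beyond what the
package's tests and acceptance script themselves compute.

## Geometric contact definitions

Two detectors operate on single frames of a stripped (solvent-free,
whole-molecule) trajectory in Ångström coordinates:

* **Hydrogen bond** — formed iff the donor–acceptor distance is at most
  `dist_cutoff` (default 3.6 Å) *and* the angle at the donor between the
  donor→hydrogen and donor→acceptor vectors is at most `angle_cutoff_deg`.
  The default of 30° is the common analysis-tool convention for the
  acceptor–donor–hydrogen geometry; it is exposed as a parameter precisely
  because conventions differ between tools, and any re-analysis should
  state the value used. Coincident donor/hydrogen coordinates make the
  angle undefined and raise an error rather than silently passing.
* **Salt bridge (ionic contact)** — formed iff the minimum distance between
  the two sets of "last two side-chain carbons before the charged atoms"
  is strictly below `cutoff` (default 5 Å). The comparison is strict
  (`< 5`), matching the phrasing "closer than 5 Å"; the boundary case at
  exactly 5.0 Å is therefore *not* formed. Using the carbons rather than
  the charged atoms makes the criterion robust to carboxylate/ammonium
  symmetry: when several atoms resolve on a side (e.g. both carboxylate
  branches), ANY satisfying geometry forms the named contact, because
  salt bridges are reported as single named interactions.

Periodic boundary conditions are **not** applied anywhere: inputs are
assumed imaged and whole. This is deliberate — the package targets
post-processed, stripped trajectories and toy systems — and is the main
assumption to check before feeding in raw simulation output.

Atom roles (donor, hydrogen-of-donor, acceptor, charged, contact carbon)
come from an explicit topology table rather than residue templates, so toy
systems need no chemistry knowledge; `standard_roles()` provides the
conventional tags for the ionisable amino acids (e.g. LYS: NZ charged,
CD/CE contact carbons; GLU: OE1/OE2 charged, CG/CD contact carbons).

## Microstates, the conformation-space network, and basins

Each frame is labelled by a code with one binary digit per monitored
contact plus a conformation-cluster id. The cluster id comes from
single-pass **leader clustering** of the peptide backbone (N, CA, C):
scanning frames in time order, a frame founds a new cluster iff its RMSD to
every existing leader exceeds the cutoff (default 2 Å), else it joins the
first leader within the cutoff. The algorithm guarantees every frame lies
within the cutoff of its leader but not that leaders are mutually farther
apart than the cutoff — that is a property of leader clustering itself, not
an implementation accident. RMSD is computed after optimal superposition
(Kabsch with reflection correction); whether the original WORDOM
configuration fitted before computing RMSD is not documented, so fitting —
the common trajectory-clustering practice — is the default, with
`fit = FALSE` available. Cluster ids can exceed 9, so codes use a
delimited internal form `bbb|k` while reports use the compact contact
pattern (`"110"`).

The **conformation-space network (CSN)** has microstates as nodes
(population = frame count) and directed edges counting consecutive-frame
transitions within each run; self-transitions are recorded, and no edge
spans a run boundary. Every saved snapshot is used (1 ps stride by
default).

**Gradient clustering** lumps microstates into basins: each node points to
the maximum-population member of its closed neighbourhood (undirected
neighbours, self-transitions excluded from the neighbour set); chasing
pointers reaches a population local maximum, and nodes sharing a fixed
point form one basin. Determinism is enforced by the tie rules: a node
whose population ties the best neighbour's points to itself; ties between
distinct neighbours break towards the lexicographically smallest code. The
published descriptions of gradient clustering say only that rapidly
interconverting states are lumped, leaving the ascent quantity open; the
package defaults to population ascent and offers a transition-flux variant
(`mode = "transition"`: move to the strictly-higher-population neighbour
with the largest symmetrised transition count) behind a switch. Both
satisfy the same fixed-point semantics; on networks where they disagree
the flux variant follows kinetic proximity rather than density.

Coarse-graining reports basin population fractions and, for each ordered
basin pair, the total inter-basin transition count divided by the total
number of transitions. Each basin is labelled by its most populated
member's contact pattern, with the minor patterns listed alongside —
metastable configurations may contain heterogeneous contact patterns.

Equilibration handling: `discard_equilibration()` drops all frames with
time < 50 ns by default (the conventional guard against starting-structure
bias); a burn-in at least as long as the run is an error rather than an
empty trajectory.

## Windowed RMSF

The trajectory is cut into consecutive non-overlapping windows of the
requested length; a trailing partial window is dropped (the simplest
unbiased choice; overlapping windows would correlate the averaged values).
Within a window, every frame is superposed onto the window-mean structure:
the mean is seeded by fitting all frames onto the first frame and is
re-estimated once from the fitted frames before the final fit. Seeding from
the first frame (rather than the mean of unfitted frames) makes the whole
procedure exactly equivariant under rigid-body motion of the input — a
property the tests check to 10⁻⁶ Å. Per-atom RMSF is the root
time-mean-square deviation from the window-mean position; per-residue
values average each residue's N, CA and C; profiles average over windows
and then over runs (for equal-length runs, pooling windows across runs and
averaging within runs give identical means, so the simpler pooling is
used). The superposition fit can use a different atom set than the
reported one (`fit_selection`), the standard way to avoid a mobile loop
dragging the frame of reference: fit on the stable domain, report
everything.

For isotropic Gaussian jitter of σ per coordinate the per-residue RMSF has
closed form σ√3; the fit absorbs six rigid degrees of freedom, shrinking
the expectation by a factor ≈ √(1 − 6/(3N)) for N fitted atoms, so the
closed form is recovered within 2% only for N ≳ 50 — the acceptance check
uses a 90-atom system and 10⁴ frames. Short windows cannot see motions
slower than the window; the tests verify this on a planted slow
square-wave displacement, mirroring the way 3 ns windows suppress loop
flexibility differences that 200 ns windows reveal.

## Family sequence statistics

Paralog redundancy is removed by grouping sequences whose pairwise identity
(identical residues over positions where neither has a gap; a pair with no
gap-free overlap gets identity 0 with a warning) reaches 50%, taking the
connected components of that graph (single linkage — the natural reading
of "groups of paralogs"; complete linkage is available behind a flag), and
weighting each member of a k-group by 1/k.

Loop enrichment of a residue class (default D/E) uses a pooled 2×2 table —
class/other × loop/non-loop — over unweighted integer residue counts, with
the one-sided Fisher exact (hypergeometric upper tail) P for
over-representation; the direction is one-sided because the hypothesis is
directional. Weighted frequencies are reported alongside, since the
headline percentages are paralog-weighted but the exact test requires
integer counts; combining the two exactly is an open problem the package
does not pretend to solve. A pooled table (rather than per-column tests)
was chosen because the question is about the loop region as a whole. Note
that the one-sided P at a perfectly balanced table is ≈ 0.67, not 1.0: the
upper tail includes the observed table's point mass.

Helical-propensity profiles take per-domain tables for up to 20 residues
downstream of the domain C-terminus (produced upstream by a secondary-
structure predictor and consumed as TSV), zero-pad positions past a
protein's C-terminus, split domains by the residue class at a chosen
alignment column (ILE/LEU/VAL vs ALA by default), and average per position
with paralog weights. Domains absent from the tables are dropped from both
classes with a warning rather than silently zero-filled.

Permutation p-values for class contrasts reshuffle the class labels at the
paralog-group level (a group's label is its members' majority label), so
that the same phylogenetic redundancy the weights remove cannot
manufacture significance; member-level shuffling exists behind a flag. The
p-value uses add-one smoothing, p = (1 + #{perm ≥ obs})/(1 + n), hence is
never exactly 0, and under the null it is uniform on its discrete support
— verified by a KS test over 200 synthetic null datasets.

## Synthetic generators: what they emulate, and what they do not

`gen_markov_trajectory()` produces a 4-residue peptide facing a 3-residue
loop, with only the atoms the detectors need. Binding modes follow a
user-specified Markov chain (default: three modes with contact patterns
110, 001 and 100, stay-probability 0.99 per 1 ps frame and asymmetric
exchange, giving a non-uniform stationary distribution). Each mode's
geometry template realises exactly its mapped contacts at zero jitter —
formed contacts sit ≈ 2.5 Å inside the 5 Å cutoff, broken ones ≥ 1.5 Å
outside — and modes differ by an internal backbone zig-zag (3 Å amplitude
steps) that superposition cannot remove, so the leader clustering separates
them at the 2 Å cutoff. Per-frame coordinates add i.i.d. Gaussian jitter
(default σ = 0.15 Å, small against those margins, so digit flips are
negligible at the default).

Mode switches route through one-frame **doorway** sub-states: contacts
break (pattern 000) while the backbone still holds the outgoing mode's
conformation, and the next frame lands in the new mode. This encodes the
physical ordering "contacts break before the backbone moves", and it is
what makes the three modes recoverable as three distinct basins: gradient
clustering can only separate attractors that are not direct network
neighbours, and instantaneous mode→mode jumps would wire every attractor
to every other. `expanded_transition_matrix()` exposes the exact
(2k-state) chain actually simulated, so closed-form oracles — the
stationary distribution and autocorrelation-aware standard errors
(`markov_stationary()`, `markov_indicator_se()`) — come from the generator
specification, never from the data being tested. The naive binomial
standard error is wrong for occupancies estimated from autocorrelated
frames; the package computes the asymptotic variance from the lag-summed
autocovariance of the state indicator under the chain.

What the trajectory generator does **not** emulate: force-field energetics,
solvent, realistic side-chain geometry, peptide unbinding, or the
tens-of-nanoseconds interconversion times of full simulations (dwell times
are scaled to ~100 ps so that 10⁵-frame runs contain thousands of
transitions). Passing the recovery tests therefore demonstrates the
statistical machinery — detection, encoding, network construction, basin
assignment, error calibration — not the physics of any real PDZ complex,
whose headline occupancies and mode populations depend on trajectories
this package does not ship.

`gen_msa()` plants paralog groups as point-mutant clouds around random
ancestors (mutation rate capped at 0.2 so within-group identity stays
above the 50% grouping cutoff by construction) and multiplies the D/E
probability in designated loop columns by an enrichment factor
(renormalising the rest; factors pushing the probability past 1 are
rejected). `gen_propensity_tables()` draws clipped-Gaussian propensities
around per-class means with an optional truncated fraction of domains. The
generated families have no real phylogeny, alignment gaps or composition
biases beyond the planted ones; conclusions about real curated alignments
require the real data.

## Problem sizes and numerical conventions

Units are fixed package-wide: Ångström coordinates, picosecond times,
0-based frame and atom indices, nanosecond burn-ins and window lengths.
The test suite and acceptance script use: 1000 random geometries per
detector oracle; 100 random networks of ≤ 12 nodes for the gradient
oracle; 10⁵ frames for Markov recovery (3-SE criteria with
autocorrelation-aware errors); 10⁴ frames × 90 atoms for the RMSF closed
form (2% tolerance); all 2×2 tables with total ≤ 30 for Fisher exactness;
200 null datasets × 199 permutations for uniformity. Superposition rejects
fewer than 3 points and collinear point sets (the rotation is
undetermined); degenerate Fisher tables (an empty margin) and all-gap
column sets are errors, not NaNs.
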