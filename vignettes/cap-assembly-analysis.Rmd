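---
title: "Inferring cap-domain assembly in disulfide-free K2P channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cap-domain assembly in disulfide-free K2P channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(k2pcap)
```

Two-pore-domain (K2P) potassium channels are dimers whose two extracellular
M1-P1 linkers fold into a helical "cap" sitting above the selectivity
filter.  In most K2P channels the tip of the cap carries a cysteine forming
an inter-subunit disulfide bridge; the TASK-1/3/5 subfamily lacks that
cysteine, so something else must hold the two caps together.  `k2pcap`
implements the computational reasoning used to work that question out: a
coiled-coil hypothesis tested by sequence analysis, an alanine-scanning
screen decomposed into trafficking versus gating defects, contact analysis
of candidate dimer structures, and a concordance score that asks which
candidate structure best explains the mutagenesis hits.  Every stage can be
exercised on synthetic inputs with known ground truth.

## Heptad registers and the coiled-coil score

A coiled coil shows a seven-residue periodicity conventionally labelled
`a`-`g`, with hydrophobic residues at `a`/`d` packing the helix-helix core
and charged residues at `e`/`g` providing specificity.  `assign_heptad()`
is plain modular arithmetic: given an anchor position defined to be an `a`
site, every other position gets its letter with period 7.
`count_site_classes()` then tallies how many screen hits land on a chosen
set of sites -- the classic test of whether a functional pattern follows a
coiled-coil geometry.

`coils_score()` implements the Lupas sliding-window method.  For a window
of $w$ residues and one of the seven possible registers, the score is the
weighted geometric mean of per-residue propensities
$$S=\Big(\prod_i p_i^{w_i}\Big)^{1/\sum_i w_i},$$
where $p_i$ is the bundled propensity of residue $i$ at its heptad position
and $w_i$ is 2.5 at `a`/`d` and 1 elsewhere.  Each sequence position
reports the maximum over all windows covering it and all registers.
`coils_probability()` converts the score to a probability using a
two-Gaussian decision model, $p = G_{cc}(S)/(G_{cc}(S)+G_g(S))$, where
$G_{cc}$ and $G_g$ are Gaussian densities fitted to coiled-coil and
globular score distributions.  The probability is exactly 0.5 where the two
densities cross and saturates quickly above the crossover -- which is why a
sequence can lose seven residues to alanine and keep $p \approx 0.999$:
alanine itself has benign propensities at most heptad positions, so the
*score* barely moves even though the *residues* that mattered functionally
are gone.  This saturation is the method's well-known blind spot and is
precisely the behaviour the package needs to reproduce: a high coiled-coil
probability is not evidence that the predicted interface is what holds the
protein together.

Tunable parameters and defaults: window 28 residues (the most specific of
the three calibrated windows; 14 and 21 are available), matrix `MTIDK`
(derived from a broader protein set than the older `MTK`, which is also
bundled), a/d weighting 2.5.  These are the conventional defaults of the
sliding-window method; the original analysis did not record which settings
produced its figures, so all three knobs are exposed as arguments and as
`coils` CLI flags.  Propensity values of zero (e.g. proline at `a`) force a
window score of 0 rather than being floored.  Ambiguity codes (B, Z, X)
are rejected rather than imputed: silently scoring an unknown residue as
"average" would bias windows upward.

The bundled calibration tables follow the published method's structure and
were transcribed without access to the original distribution files; the
package treats them as its own calibration, all derived test expectations
are computed from these tables, and both tables are exported
(`coils_matrix()`, `coils_gaussian()`) so users can substitute their own.

## Sequon scanning

`scan_sequons()` finds N-glycosylation consensus motifs N-X-S/T with X not
proline.  A proline immediately *after* the S/T also abolishes
glycosylation without breaking the motif match, so such sequons are kept
but flagged (`disrupted_by_proline`).  Keeping rather than dropping them
matters for the mutagenesis logic: a Q-to-P mutation three residues after
the asparagine removes the glycan while leaving the N and S structurally
intact, which is exactly the control that separates "glycosylation lost"
from "structure perturbed".

## Screen statistics

Oocyte expression varies strongly between frogs and injection days, so
`normalize_to_reference()` divides each measurement by the wild-type mean
*of its own batch* by default (global normalisation is a fallback for
single-batch data).  The reference construct's mean relative value is 1 by
construction.  Per-construct summaries are reported as mean ± SEM.

The key derived quantity is the **conductivity** ratio: relative current
divided by relative surface expression.  A mutant that traffics poorly but
gates normally loses current and surface expression in proportion, so its
conductivity stays near 1; a mutant that reaches the membrane but cannot
conduct keeps normal surface expression and shows a conductivity well
below 1.  The ratio deliberately does not distinguish single-channel
conductance from open probability.  `classify_mechanism()` turns this into
labels with three thresholds: relative current below 0.3 of wild type
counts as loss-of-function, a conductivity inside [0.5, 2] counts as
normal gating, and relative surface below 0.3 counts as reduced.  The
original report never states numeric cutoffs; these defaults were chosen
once as round values that cleanly separate ~90% reductions from ~20%
reductions at screen-typical noise, and they are arguments everywhere they
are used.  Hits are flagged at relative current < 0.3 with p < 0.001
(unpaired two-tailed Student's t against wild type, pooled variance; Welch
and Holm-corrected variants are available behind flags but off by default,
matching the per-construct reporting convention of this field).

Degenerate t-test inputs are handled explicitly rather than erroring:
identical constant groups give p = 1, constant groups with different means
give p = 0.

`dominant_negative()` quantifies co-expression suppression as
$1-\bar x_{co}/\bar x_{ref}$; negative values are reported as enhancement,
since co-expressing a healthy subunit typically *adds* current.

## Contact analysis on multi-model structures

Trajectories are multi-model PDB files (MODEL/ENDMDL blocks, file order =
frame order, numbering taken verbatim, hydrogens ignored).  Distances are
measured between one predefined **reference carbon** per residue: the
side-chain carbon just before the last branch point, so the measured point
does not depend on which branch happens to swing closer.  Unbranched side
chains use their terminal carbon; glycine falls back to CA.  Two entries
deviate from the mechanical rule and are shipped as documented overrides:
methionine uses CG (staying before the thioether sulfur rather than the
terminal methyl) and proline uses CG (its ring closes onto the backbone
nitrogen).  The table is a plain named vector and every distance function
accepts an edited copy, because reasonable structural biologists disagree
about these choices.

An interaction is called when the **mean** distance over frames is at most
6.0 Å, inclusive at the boundary.  The cutoff is deliberately more remote
than a direct carbon-carbon contact (~4 Å) because the reference carbon is
generally not the closest atom of the side chain and hydrogens are not
represented; `min_sidechain_distance()` provides the complementary check
that called pairs do approach much closer when all side-chain heavy atoms
are considered.

One representational choice needs explanation.  In real coordinates the
two symmetry-related copies of an inter-subunit contact -- residue $i$ on
chain A with $j$ on chain B, and $j$ on A with $i$ on B -- are distinct
measurements.  `contact_matrix()` defines the cell of the unordered pair
$\{i,j\}$ as the per-frame **minimum** of the two copies (and likewise the
minimum over the two chains for intra-subunit cells).  This makes the
matrix exactly symmetric by construction, keeps the diagonal meaningful as
homotypic pairs, and asks the biologically relevant question ("does this
contact exist somewhere in the dimer?") rather than averaging over a
labelling artefact.  The square export layout mirrors the conventional
publication table: inter-subunit cells on and below the diagonal,
intra-subunit cells above it.

Stability checks use `rmsd_kabsch()` (SVD-based optimal superposition with
reflection correction) and `frame_rmsd()` for per-frame series against a
reference frame.  `frame_count()` encodes the sampling convention
duration/interval with no frame at $t=0$: 10 ns sampled every 4 ps yields
exactly 2500 structures, and the off-by-one alternative would contradict
that count.

## Concordance scoring

`score_model()` connects structure to function: it counts inter-subunit
interaction calls whose **both** residues are mutagenesis hits and reports
which hits are covered.  Homotypic diagonal calls count once and cover one
hit.  Intra-subunit calls are tallied but excluded from the score -- a
contact inside one subunit cannot explain a dimerisation defect.
`rank_models()` orders candidate models by call count, breaking ties by
the mean inter-subunit distance over all hit pairs (smaller distances =
the interface concentrates the hits better).  The tie-break is a
documented heuristic, not a significance statement; no null model is
claimed, and the composite count+coverage report is this package's
formalisation of "agreement with the screen".

## What the synthetic data emulate -- and what they do not

`make_toy_cap()` builds two ideal α-helices (φ = −57°, ψ = −47°, giving
~1.5 Å rise and ~100° rotation per residue) with full side-chain heavy
atoms from idealised internal coordinates (fixed trans-dominant rotamers),
then rigidly places chain B so that every planted reference-carbon
distance is met to within 0.05 Å, via multi-start least squares over the
six rigid-body degrees of freedom.  Distance sets that no rigid placement
can realise raise an error -- which is scientifically informative: a
straight-helix dimer *cannot* reproduce contact patterns that require the
real cap's helix-turn-helix, domain-swapped connectivity (for instance a
48-62 cross-contact coexisting with a full ladder of homotypic contacts).
The package's demo preset therefore plants the realisable subset of the
canonical contact pattern and lets the missing hit speak for itself.

`jitter_trajectory()` adds i.i.d. Gaussian displacements per atom and axis.
It reproduces the *statistics* a distance pipeline must handle (a planted
pair at mean $d_0$ acquires distance SD $\approx \sqrt2\sigma$, plus the
small convexity bias $\sigma^2\!/d_0$ of a norm under isotropic noise) but
none of the physics: no correlated motions, no bonded constraints, no
membrane.  Passing the planted-recovery tests therefore shows the
*measurement machinery* is correct, not that real trajectories would be
this well behaved.

`simulate_screen()` draws multiplicative lognormal noise (expression data
are positive and right-skewed) parameterised so the noise factor has mean
1, with a per-batch lognormal wild-type scale.  Defaults -- 20 oocytes per
construct, CV 0.3, batch SD 0.2 on the log scale -- are typical of
two-electrode voltage-clamp screens of well-expressing channels.  Planted
effect sizes in the demo preset (93% current reduction for a/d-site
mutants, 20% for f-site, proportionate surface loss for cap mutants,
preserved surface for gating mutants) mirror the effect structure of the
motivating screen.  Note one statistical subtlety the tests respect:
per-batch normalisation shares the wild-type mean's sampling error across
all constructs of a batch, so recovered relative values are *correlated*
and their standard error includes a reference term,
$\mathrm{SE} \approx \hat r\,\mathrm{CV}\sqrt{1/n_m + 1/n_{wt}}$.

All generators take explicit seeds, never touch the caller's RNG state,
and are bit-reproducible.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → coils → screen → contacts → concordance
with a single validated configuration (YAML-serialisable, CLI-overridable)
and writes an MD5-hashed manifest; identical configurations reproduce
identical hashes.  The bundled demo runs a 33-residue cap region per chain
(residues 45-77), 150 trajectory frames at σ = 0.25 Å, and 20 oocytes per
construct in 2 batches -- sizes chosen so the whole pipeline completes in
seconds while keeping every estimate comfortably inside its noise budget;
the test suite uses the same or smaller sizes with 50-100 replicate seeds
where rates are asserted.

## Known limitations

* The coiled-coil calibration tables are transcriptions (see above); do
  not quote absolute probabilities from them for publication without
  re-deriving the Gaussian constants for your own sequence set.
* The contact caller analyses exactly two chains; higher-order assemblies
  need pre-splitting.
* Idealised side-chain geometry means synthetic structures are sterically
  naive (atoms may approach unphysically); they are measurement fixtures,
  not models.
* The concordance score is descriptive.  It ranks candidate structures; it
  does not test them.
* Real MD-scale results (force fields, membranes, 10-100 ns dynamics) are
  intentionally out of scope; the package consumes such trajectories as
  multi-model PDB but cannot generate them.
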