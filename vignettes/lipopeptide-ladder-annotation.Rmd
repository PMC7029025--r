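---
title: "Annotating lipopeptide isoform families from homolog ladders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating lipopeptide isoform families from homolog ladders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipoladder)
```

## The mass model

Every mass in the package is monoisotopic and every observed ion is
treated as singly protonated, [M+H]⁺ — the regime of a positive-mode
electrospray Q-TOF looking at 1 kDa lipopeptides. The element set is
fixed to C, H, N, O, S; isotope envelopes, higher charge states and
adducts other than protonation are out of scope. The atomic and residue
mass tables ship as versioned TSV files under `extdata/` so that every
numeric expectation in the test suite can be pinned to an auditable
constant. Leucine and isoleucine are isobaric and collision-induced
dissociation cannot tell them apart, so sequences conventionally use
`L`.

A lipopeptide hypothesis (`lipopeptide_spec`) is a peptide sequence, a
β-hydroxy fatty-acid tail length in carbons, and a topology. The tail is
book-kept as the free saturated acid CₙH₂ₙO₃ (each double bond removes
two hydrogens); the amide bond to the N-terminal residue and the lactone
ester are explicit water losses:

- linear: M = Σ residues + tail (the amide condensation consumes
  exactly the water that the free termini would otherwise add),
- cyclic: M = linear − H₂O.

This forces two identities that the test suite checks to 1e-9 Da on
randomly generated hypotheses: linear − cyclic = 18.0105646 Da for any
spec, and +1 tail carbon = +14.0156500 Da at fixed topology. Vendor
peptide-sequencing software instead reports the tail as a "modification
formula" with its own water bookkeeping; those printed labels (e.g.
`C12H22O4`) are accepted as input via a shipped conversion table
(`tail_label_to_carbons()`) but never used in arithmetic, because their
water conventions are not defined precisely enough to be audited.

### The composition ambiguity

`composition_fit()` ranks candidate hypotheses against an observed m/z
by absolute ppm error. The bundled peak list is a case in point for why
the package reports fits rather than adjudicating them: the published
masses of this family sit ~16 Da (one oxygen) away from the pure-Leu
heptapeptide composition asserted alongside them, but within ~27 ppm of
the surfactin-like composition with one glutamate (`ELLVDLL`). The
default ppm window for flagging a match is therefore 30 ppm — wide
enough to admit the data the package was built around — and both
sequence hypotheses can be carried through the pipeline side by side.
Nothing downstream of `composition_fit()` depends on which composition
is right: ladder detection, topology calls and tail propagation operate
on observed mass *differences*, which is precisely why the method is
robust to calibration offsets.

## Ladder detection and annotation

`detect_ladders()` connects peak pairs whose m/z difference matches the
methylene spacing (edge kind `CH2`) or the water spacing (`WATER`)
within a tolerance, and takes connected components as isoform families.
Default tolerances are 0.03 Da for both edge kinds: the bundled data
show per-injection mass SDs of 0.01–0.02 Da while the observed ladder
spacings deviate from the canonical values by at most 0.011 Da, so
0.03 Da accepts all genuine edges with margin without reaching the next
plausible spacing. Edge conflicts — one peak matching two candidate
partners of the same kind and direction — are resolved greedily: smaller
mass residual wins, ties broken by smaller retention-time gap, then by
peak id, so the output is deterministic and invariant under permutation
of the input rows (a property the suite tests directly). Singletons are
first-class families: real peak lists contain contaminants.

Topology is called from water edges (heavier member linear, lighter
cyclic); peaks connected only by CH2 edges default to cyclic candidates,
isolated peaks stay unknown. Retention order — linear forms eluting
earlier, mass increasing with retention within a class — is used as
*corroboration only*: violations append warnings but never remove an
edge, because retention times are instrument- and gradient-specific.
MS2 evidence, when supplied, takes precedence over the MS1 call
(`reconcile_topology()`), since the ring-opening daughter is direct
structural evidence while the water edge is inferential; conflicts are
recorded in the family's warning list rather than silently resolved.

Tail carbon counts cannot be read off absolute masses (see the
composition ambiguity above); they are *propagated* from one anchored
member of independently known composition: +1 carbon per CH2 edge toward
the heavier member, unchanged across water edges. If two propagation
paths disagree the function stops and names the offending cycle — a
disagreement means the edge graph is chemically impossible, and
continuing would silently corrupt every downstream call. Designations
follow the field's convention: cyclic members lettered A, B, C, … by
increasing protonated mass, linear members taking their cyclic water
partner's letter with an `_L` subscript. A linear member with no cyclic
partner (possible when MS2 overrides an MS1 call) is lettered by the
rank its tail count would take among the cyclic members, with a warning.

### The ring-opening topology test

A lactone-cyclised depsipeptide opens hydrolytically under CID before
fragmenting, so its MS2 spectrum contains a daughter at parent + H₂O.
`topology_test()` calls cyclic if any fragment lies within
`daughter_tol` of that value, linear if fragments exist but none does,
inconclusive on an empty spectrum. The default `daughter_tol` is 0.2 Da,
an order of magnitude looser than the b/y matching tolerance
(`frag_tol`, default 0.05 Da): daughter ions adjacent to an intense
precursor are poorly centroided in practice, and the reference data this
package reproduces show exactly that — a daughter printed 0.11 Da above
the exact +H₂O value. Ring opening is modelled only at the ester bond;
an amide-opened linearisation would add no water and produce no such
daughter.

## What the synthetic generator emulates

`simulate_family()` generates the peak-list structure the detector
assumes: a family of cyclic homologs over a tail range with linear
partners per a topology plan, retention times increasing ~0.9 min per
tail carbon with linear forms offset −3.1 min (reproducing the
qualitative elution structure of the reference data: sub-minute to
~1.3 min gaps between cyclic homologs, linear forms ~3 min early),
log-uniform intensities, and optional uniformly scattered contaminant
peaks. Defaults are the reference family: `LLLVDLL`, tails 12–15, linear
partners for the two longest tails, total mass SD 0.015 Da.

The mass-error model deserves its own paragraph. The per-peak SD across
injections (`mass_sd`, default 0.015 Da, matching the reference data) is
decomposed into a per-injection calibration drift shared by all peaks of
one simulated injection plus an independent per-peak residual;
`mass_shared_frac` (default 0.8) is the shared fraction of the variance.
This is how time-of-flight instruments actually behave — absolute masses
drift with calibration while mass *differences* within one spectrum stay
tight — and it is visible in the reference data, where the six printed
ladder spacings deviate from canonical by ≤ 0.011 Da (RMS ≈ 0.006 Da,
on means of three injections) although the per-injection SDs are up to
0.021 Da. Under a purely independent error model those spacings would
carry √2 × 0.015 ≈ 0.021 Da of noise each, and observing all six within
0.011 Da would be a ~0.4% event; the shared-drift decomposition with
√(1−0.8) × 0.015 ≈ 0.007 Da of independent residual reproduces the
observed delta precision. The shared fraction was fixed from that
argument, not fitted to detector performance. Ladder detection operates
on deltas, so its recovery rate is governed by the residual component
only — which is also why the method works on real instruments whose
absolute calibration is an order of magnitude worse than their
within-spectrum precision.

What the generator does *not* emulate: chromatographic peak shapes,
isotope envelopes, charge states above 1, co-eluting isobars, and
intensity-dependent mass error. Passing recovery tests on synthetic
data therefore demonstrates the correctness of the graph logic and its
noise tolerance, not readiness for arbitrary raw data; on a real file
the user still owes the pipeline a centroided, deisotoped peak list.

`simulate_ms2()` drops a seeded random fraction of the theoretical b/y
ions, jitters the survivors, and appends the ring-opened daughter for
cyclic precursors; dropout is applied to the b/y ladder only, so the
topology test can be exercised independently of fragment coverage.

## Validation problem sizes

The shipped suite validates the pipeline at the scale the method is
meant for: the six-peak reference family for the end-to-end annotation;
100 randomly laid-out noiseless families (tails starting at 8–14, 2–4
rungs, random cyclic/both plans) for exact planted-truth recovery; 200
seeded families at mass SD 0.015 Da for member-level recovery ≥ 95%;
100 random hypotheses for each mass identity at 1e-9 Da; and 1000-draw
bootstraps for the structure–activity trends. These sizes keep the whole
suite under a minute while leaving each property no room to pass by
luck.

## Structure–activity analysis

With four tail lengths and an ordinal claim — longer tails shift potency
from bacteria toward fungi — the right correlation is Spearman's rank
rho, not Pearson: no linearity is asserted and n = 4 cannot support one.
`sar_trend()` reports rho and a direction, with |rho| < 0.5 called flat;
a constant response is an error rather than rho = 0, because an
undefined rank correlation should not masquerade as evidence of
flatness. `selectivity_index()` is the per-isoform ratio
MIC(fungi)/MIC(bacteria); the crossover is the adjacent pair of isoforms
(by tail length) whose ratios bracket 1. Since only triplicate means and
SDs are published, `bootstrap_trend()` propagates uncertainty by normal
resampling of each mean with its printed SD — a summary-statistics
bootstrap, the best available without raw replicates — and reports the
fraction of resamples preserving the sign of the point-estimate rho.
One bookkeeping note carried over from the source data: the fungal
inhibition zones were published labelled as a radius while the bacterial
ones are diameters; the bundled table stores the numbers verbatim with a
`zone_measure` column flagging the discrepancy, and no analysis in the
package compares zones across organism classes.

## Known limitations

- Tail lengths are only ever relative to the anchor; an anchor
  mis-assignment shifts the whole family by a constant.
- MS1 alone cannot call a linear form that lacks its cyclic partner in
  the same list; such peaks are reported as cyclic candidates until MS2
  evidence arrives.
- Branched tails are invisible (mass-identical to straight chains), and
  stereochemistry is entirely out of scope.
- The greedy edge-conflict resolution is locally optimal; a pathological
  list could in principle admit a better global ladder assignment, but
  the determinism it buys is worth more at the densities this method is
  used at.
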