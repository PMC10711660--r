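---
title: "Mapping domain-SLiM interfaces by fragment-scan consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping domain-SLiM interfaces by fragment-scan consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimscan)
```

## The problem

Many protein interactions are mediated by a short linear motif (SLiM): a
handful of residues in an intrinsically disordered region that dock into a
pocket on a folded partner domain. Complex-structure predictors can
propose such interfaces, but a single prediction of a full-length
disordered tail against a multi-domain partner is often low-confidence and
unstable from run to run. slimscan implements a consensus strategy around
this weakness: instead of asking one prediction to be right, it tiles the
disordered tail into many overlapping fragments, pairs every fragment with
every candidate bait domain, and asks which residue pairs are predicted to
touch *consistently* across the ensemble of runs.

The worked configuration in the package follows a silkworm piRNA-pathway
pair: the 101-residue protein BmGtsf1L, whose 39-residue C-terminal tail
(residues 63-101) carries a tryptophan-anchored motif around W99, screened
against the three extended Tudor (eTudor) domains of BmVreteno. The
packaged FASTA fixture (`slimscan_fasta()`) holds both full-length
sequences, and all residue numbering in the package is 1-based protein
numbering, so positions like W99 or S744 mean what a structural biologist
expects.

## Fragment tiling

`scan_config()` / `enumerate_fragments()` tile the tail from up to three
anchors — start, middle and end — with nominal lengths
`init_len, init_len + step, ...` (defaults 5 and 5, in residues). The
series stops at the first length that reaches the tail length; that final
fragment is clipped to the whole tail. For a 39-residue tail this gives 8
nominal lengths (5..40, the last clipped to 39) per anchor, 24 fragments,
and 72 runs against three bait domains.

Three conventions here were genuinely open and are package decisions:

* **Middle anchoring.** No centring rule is implied by "a fragment at the
  middle", so the package centres on `ceiling(L/2)` with a left-biased
  half-width, and resolves boundary collisions by shifting the span —
  never shortening it — so that all same-length fragments are comparable.
* **Coincident fragments are kept.** At the full tail length all three
  anchors produce the same span. They are retained as separate runs
  rather than deduplicated: prediction is stochastic, so replicate
  submissions of the same span are informative, and this is the only
  convention under which 8 lengths x 3 anchors x 3 domains reproduces a
  72-run manifest.
* **The series stops at the first clipped fragment**; no lengths beyond
  the tail are generated.

`build_manifest()` forms the Cartesian product with the named bait
domains in a deterministic order (domain, then anchor, then length), so
re-running a configuration is byte-identical.

## Contact extraction from predicted models

Each run directory is expected to contain model files plus ranking
metadata; `select_top_model()` returns the first-ranked model only —
lower-ranked models are never mixed in. Two metadata dialects are read:
a compact native `metadata.json` (`ranking`, `confidence`, optional
`pae`), and the AlphaFold `ranking_debug.json` layout where the top model
is `ranked_0.pdb` by construction. Model confidence is read as-is and
never recomputed; no confidence- or pLDDT-based filtering is applied.

`interchain_contacts()` implements the model contact rule: residues from
opposite chains are in contact when at least one heavy atom of one is
**strictly less than** 5 Å (default) from a heavy atom of the other.
"Heavy" means element not H/D, with elements taken from the PDB element
column or inferred from atom names when that column is absent (predicted
models often omit it; the inference treats CA/CD/NA as carbon/carbon/
nitrogen atom names, not metals). Distances are computed in double
precision over all inter-chain atom pairs; ties at exactly the cutoff are
excluded by the strict inequality. Alternate locations beyond the first
are discarded on reading.

Fragment models number their residues fragment-locally, so
`remap_contacts()` shifts prey indices by the fragment's global start and
bait indices by the domain start before runs are overlaid.

## The consensus matrix and hotspots

For each bait domain, `accumulate_runs()` builds
`freq[i, j] = hits[i, j] / denom[j]`, where `hits` counts runs in which
pair `(i, j)` is in contact and `denom[j]` counts runs whose fragment
covers prey residue `j`. Because every run contains the full bait domain,
"runs containing the pair" reduces to prey coverage; this covering-run
denominator is the default, and `denominator = "all"` is available as a
sensitivity alternative. One matrix is produced per bait domain — no
cross-domain pooling. `observed_submatrix()` restricts the axes to
residues observed at least once in contact, which is how consensus
heatmaps are conventionally displayed.

A *hotspot* (`detect_hotspots()`) is a maximal 8-connected component of
cells with `freq >= 0.5` containing at least 3 cells. The threshold,
connectivity and minimum size are an operationalisation of a
qualitative notion — a patch of residue pairs predicted in contact in
most covering runs — and all three are exposed as parameters. Isolated
single-run coincidences have `freq = 1/denom`, which for reasonably
covered residues falls well below the threshold, and the minimum size
suppresses isolated high-frequency cells at poorly covered tail edges.

## Trajectory analysis

The MD-facing half consumes replicate trajectories of a domain/peptide
complex as multi-model PDB (or a per-frame coordinate table keyed to a
topology). The trajectory contact rule is **inclusive**: residues are in
contact in a frame when any atom pair is within 4.5 Å. Heavy atoms only
is the default for consistency with the model rule — force-field
trajectories carry hydrogens, and `heavy_only = FALSE` restores the
all-atom reading, which is left open by the usual phrasing of the rule.

`trajectory_contact_map()` converts a replicate into per-pair frame
fractions; `average_maps()` takes the elementwise mean across replicates
started from the same structure; `marginal_profiles()` sums frequencies
along each axis to give the relative interaction probability per residue
(sums of probabilities, so values can exceed 1).

`hbond_series()` records the donor-acceptor distance per frame and calls
the bond engaged when the distance is at most 3.5 Å and, when a hydrogen
is supplied, the D-H-A angle is at least 150 degrees. These defaults are
a standard geometric hydrogen-bond criterion; both knobs are exposed,
and a distance-only fallback applies when hydrogens are absent.

`classify_anchored()` asks, per replicate, whether the motif anchor
residue's side-chain heavy atoms stay within 4.5 Å (the contact rule,
reused deliberately) of any pocket heavy atom in at least half of the
frames. The 0.5 frame-fraction threshold is the package's
operationalisation of "anchors for the bulk of the simulation"; a
residue with no side-chain heavy atoms (glycine) is rejected rather than
silently classified.

## Rigid superposition

`kabsch_superpose()` is a from-scratch SVD-based least-squares
superposition: proper rotations only (the determinant correction forbids
reflections), with errors for fewer than 3 points, mismatched lengths and
collinear sets (where the rotation about the axis is undetermined; the
second singular value is tested against `1e-8` of the largest).
Range-based superposition (`superpose_ranges()`) takes explicit residue
correspondences and defaults to alpha-carbons; sequence-independent
alignment search is out of scope, since the residue pairings of interest
are stated explicitly in practice. In tests the implementation is checked
against an independent oracle: a coarse Euler-angle grid search refined
by Nelder-Mead.

## What the synthetic data emulates — and what it does not

`make_toy_complex()`, `make_mock_scan()` and `make_toy_trajectory()`
exist so the full pipeline runs with no prediction or simulation engine.
Residues are 1-4 pseudo-atoms; planted bait/prey pairs are realised at
exactly `contact_distance` (default 4 Å) and every other inter-chain pair
sits at or beyond `background_min_distance` (default 8 Å), so any cutoff
between the two recovers exactly the planted pairs. Contact noise is
independent Bernoulli per off-pair per run (`noise_rate`) — the simplest
null under which the consensus denominator logic is testable. Mock scans
plant motif-pocket contacts only in runs of the pocket-bearing domain
whose fragment covers the motif, permute model file names so that
ranking-based selection is actually exercised, and draw confidences
higher for motif-covering runs than background ones, mirroring the
contrast real ensembles show. Toy trajectories interpolate nothing: bound
frames use the complex geometry, unbound frames translate the prey chain
away, `unbinding_frame` marks the last bound frame (so an unbinding
frame at the midpoint of an even-length trajectory gives an in-pocket
fraction of exactly one half), and Gaussian jitter with configurable SD
is added per coordinate.

These fixtures share only their *distance statistics* with real data.
They have no physical geometry, no rotamers, no correlated noise, no
partial or fuzzy interfaces, and prediction "confidence" is a planted
number, not a calibrated score. Passing tests therefore demonstrate that
the bookkeeping — tiling, ranking, remapping, denominators, component
detection, frame counting — is correct, not that any particular
predictor or force field would reproduce a given biological interface.
A pocket of at most 3 residues can be fully paired per motif residue
(the 4-pseudo-atom budget); larger planted pockets must be split.

## Test and validation scale

The shipped test suite exercises: oracle equivalence of contact
extraction against a brute-force atom-pair scan on 100+ random models
under both distance rules; end-to-end recovery of a planted
motif-pocket hotspot from ten seeded 72-run mock scans at noise rate
0.05; a 10-replicate anchored/unanchored classification (9 bound, 1
unbound, 20 frames each); and Kabsch exactness plus oracle agreement on
random 10-point clouds. These sizes keep the default suite under a few
minutes on one CPU while leaving every statistic with enough support to
be meaningful; all generators are seeded, so every reported number is
reproducible.

## Known limitations

* The consensus assigns no statistical significance to hotspots; it is a
  descriptive frequency, and the hotspot rule is a heuristic.
* PAE matrices are read and carried but not used in any decision.
* Binary trajectory formats (XTC/DCD) are not read; conversion to
  multi-model PDB or a coordinate table is expected upstream.
* The hydrogen-bond criterion is geometric only; no energetic or
  occupancy-correlation refinement is attempted.
* The tail start for the worked configuration defaults to residue 63
  (101 - 39 + 1); annotations that place the end of the structured
  region at residue 64 differ by two residues, and the tail span is
  deliberately a configuration value rather than a constant.
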