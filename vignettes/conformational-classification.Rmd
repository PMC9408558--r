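---
title: "Classifying ABC transporter structures and their conformational states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ABC transporter structures and their conformational states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcconftor)
```

## The problem

ATP-binding cassette (ABC) transporters move substrates across membranes by
cycling between two gross conformations: *bottom-open* (inward-facing, the
two nucleotide-binding domains — NBDs — separated, substrate cavity open to
the cytoplasm) and *bottom-closed* (outward-facing, NBDs dimerised, usually
ATP-bound). A functional transporter carries two NBDs and two transmembrane
domains (TMDs), encoded on one, two, or four chains. The NBDs are strongly
conserved; the TMDs are not, and their scaffolds define the structural
classes of the superfamily (Pgp-like, ABCG2-like, MacB-like, and so on).

`abcconftor` automates three linked decisions for a batch of structures:

1. **Is this a functional ABC transporter assembly?** Decided from
   profile-HMM domain hits on the chain sequences: at least two NBD hits
   and at least one TMD hit across the biological unit. Two NBD hits with
   no TMD hit is flagged `needs_review` rather than discarded, because it
   may be a transporter with a novel transmembrane fold.
2. **Which structural class?** By sequence-independent structure alignment
   against a reference library, scored with the TM-score; the best class
   wins if its score exceeds 0.6, a conventional same-fold threshold. The
   Pfam-derived class hint is recorded, and a hint/structure disagreement
   raises a flag instead of overriding the geometry.
3. **Which conformational state?** From the *conftor* measure: the two
   cross-NBD C-alpha distances between the Walker-A anchor lysine of one
   NBD (position 7 of GXXXXGKT) and the signature-motif anchor glycine of
   the opposite NBD (position 3 of LSGGQ). Each composite ATP site
   contributes one distance, so every assembly yields two values.

## The conformation rule

A structure is labelled **closed** only when *both* distances are strictly
below the 14 Å cutoff — both composite ATP sites must be formed — and
**open** otherwise. The cutoff comes from the bimodal distribution of these
distances over large structure cohorts. Two refinements:

* Distances within 2 Å of the cutoff raise a `boundary_case` flag. Near
  the cutoff the geometric measure alone is not decisive and such
  structures have historically been confirmed by visual inspection. A
  distance exactly at 14 Å is open (strict inequality) and flagged.
* The distance-based label takes precedence over the older
  nearest-reference-RMSD label, which is also computed and reported.
  Whole-structure RMSD conflates NBD separation with unrelated
  conformational noise and is known to mislabel a noticeable fraction of
  widely-open structures; a disagreement between the two labels is flagged
  `conftor_rmsd_disagreement`, never silently resolved.

Anchor residues are found by *structure* alignment of each NBD against an
annotated reference NBD, not by sequence motif search: many ABC proteins
carry degenerate Walker-A or signature motifs that sequence patterns miss,
while the fold position of the anchors is conserved. If the reference
anchor lands in an alignment gap, the nearest aligned reference position
within two residues is used and flagged `anchor_approximate`; an anchor
alignment with TM-score below 0.45 is flagged low-quality.

## The aligner

Family assignment and anchor transfer both rest on a sequence-independent,
TM-score-maximising rigid-body aligner built from three standard pieces:

* **Kabsch superposition** (SVD of the cross-covariance, reflection
  corrected) for the optimal rigid transform over a residue pairing.
* **TM-score**, `TM = (1/L) * sum 1/(1+(d_i/d0)^2)` with
  `d0 = 1.24 (L-15)^(1/3) - 1.8` floored at 0.5 Å; `L` is the reference
  length for family assignment (the question is "how much of the canonical
  fold is present"), and the query-normalised score is stored alongside.
* **Iterative refinement**: initial pairings from gapless threading at
  multiple offsets and from 20-residue fragment superpositions; each seed
  alternates superposition and dynamic-programming re-alignment (score
  `1/(1+(d/d0)^2)`, gap-open −0.6, no gap extension, free terminal gaps,
  compiled in C++) until the paired set stops changing, the score stops
  improving, or 30 cycles. The best seed by TM-score wins; ties break by
  fewer gaps, then seed order, so results are deterministic. Seeds stop
  early once one reaches TM ≥ 0.995.

One numerical choice deserves emphasis: superpositions inside refinement
are *trimmed* — the fit is recomputed on progressively tighter inlier sets
(75th-percentile distance threshold, floored at 1.5·d0). Without this, a
large rigidly displaced block such as a dissociated NBD drags the
least-squares fit away from the TM-optimal core superposition, and widely
open structures are under-scored.

On noise-perturbed fold copies the aligner matches an established external
aligner (biotite's structural-homolog superimposition) to within a few
thousandths of a TM unit; the oracle suite in the tests pins 50 such pairs
spanning noise levels from 0.2 to 2.0 Å. On essentially unrelated folds
(TM below ~0.4) heuristic aligners legitimately find different suboptimal
alignments and may differ by more; that regime does not affect
classification decisions, which only act on scores above 0.6. For
truncated substructures the planted correspondence provides a lower bound
the aligner must reach, which the tests assert directly.

## The reference library

The shipped library is **synthetic** and generated in code: three class
templates (Pgp-like, ABCG2-like, MacB-like analogues) built from
ideal-helix TM bundles with class-specific helix counts, lengths and
layouts, plus a synthetic 111-residue reference NBD (a compact six-helix
bundle) carrying the two annotated anchor residues at helix ends on the
dimerisation face. Each class entry holds an inward reference (planted
distances 40/40 Å), an outward reference (10/10 Å) and a widely-open
canonical representative (60/60 Å); family assignment scores a class by the
best of the three. The representative matters because real inward-facing
structures span opening levels from ~14 to ~86 Å, far beyond what a single
conformer can cover.

A production deployment would replace this library with curated
experimental references (one inward and one outward structure per class
and a real NBD reference with its motif residues annotated); the library
directory schema and all interfaces are identical.

## The synthetic cohort generator

Mock transporters are C-alpha assemblies: two TM half-bundles above two
rigid copies of the reference NBD. The second NBD is *placed in closed
form* — the intersection of the two spheres defined by the planted
cross-NBD distances is solved exactly — so planted conftor geometry is
recovered to machine precision before noise. Gaussian coordinate noise
(default σ = 0.3 Å, a typical coordinate-error scale for good cryo-EM
models) is then added under a fixed seed; every generator is a pure
function of its spec and seed.

Cohort defaults plant closed states at 8–11.5 Å, open states at 20–80 Å
with the second distance within 25 Å of the first (the rigid NBD geometry
caps realisable asymmetry at ~48 Å) and floored at 16.5 Å, and boundary
fixtures with one distance in 12.4–13.6 and one in 14.4–15.6 Å — pinning
the both-below rule. Open/closed draws deliberately avoid the 14 ± 2 Å
boundary band so that label-recovery checks are meaningful; the boundary
band is exercised noise-free, because the flagging rule (not noisy
measurement near the band) is what those checks pin.

What the mocks do *not* emulate: side chains, sequence realism beyond the
anchor residues, membrane context, occluded or intermediate states, and
the mass ratio of real transporters (the mock NBDs are a somewhat larger
fraction of the assembly than in real structures, which makes wide-open
mocks *harder* to classify than their real counterparts). Passing the
cohort checks therefore demonstrates the pipeline's internal correctness
and determinism, not performance on experimental data.

## Pipeline behaviour and degenerate inputs

`run_batch()` processes entries in sorted order, and each entry's failure
becomes a flagged `error:` row rather than aborting the batch; re-runs on
identical inputs are byte-identical. Hits are filtered on the per-domain
independent E-value (≤ 0.001) and profile coverage (≥ 90% of the HMM
length); overlapping same-category hits on a chain (> 50% mutual overlap)
collapse to the best E-value so one physical domain is not counted twice.
Assemblies with more than two NBD ranges are paired greedily by centroid
distance and flagged `multi_unit`; an odd NBD is left unpaired and
flagged. Multi-model files contribute model 1 only; alternate locations
keep the highest-occupancy conformer (ties by altloc letter); insertion
codes sort after the uninserted residue, alphabetically; HETATM-only
content is excluded from all C-alpha mathematics but retained in the atom
table. EcfT-like assignments would always carry an `ecf_special` advisory
flag, since ECF transporters keep their NBDs closed even without ATP.

Problem sizes used in the checked examples — 50-structure cohorts of
450–650-residue assemblies and 50 oracle alignment pairs — were chosen so
the full suite completes in minutes on a laptop while still exercising
every stage end to end.

## Known limitations

* The 14 Å cutoff and the 0.6 TM threshold are exposed as configuration
  but their defaults are the field's published values; nothing in the
  package re-derives them from data.
* Occluded and intermediate states are out of scope; the label set is
  deliberately binary plus `unassigned`.
* The Pfam catalog ships as an editable TSV; its accession list is a
  best-effort transcription and should be replaced wholesale when a
  curated profile set is available.
* Sequence-to-structure mapping trusts the `label_seq` polymer positions
  (mmCIF `label_seq_id` semantics, derived from residue order when the
  format lacks them); author-numbering gaps in PDB files without SEQRES
  information are therefore invisible to hit mapping.
* UniProt-derived metadata (taxonomy, gene and protein names) is joined
  from an optional pre-fetched sidecar table; the pipeline performs no
  network lookups.
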