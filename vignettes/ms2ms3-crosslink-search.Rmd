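---
title: "Identifying cross-linked peptides from MS2-MS3 data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cross-linked peptides from MS2-MS3 data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlms)
```

## The problem

Cross-linking mass spectrometry identifies pairs of residues that are close
in space by covalently joining them with a bifunctional reagent, digesting
the sample with trypsin, and identifying the linked peptide pairs from
tandem mass spectra. MS-cleavable cross-linkers such as DSSO and DSBSO
carry a labile bond that breaks at low collision energy, before the peptide
backbone fragments. In an MS2 spectrum this cleavage leaves each of the two
peptides carrying one of two possible remnant "arms" of the linker — a
short (light) and a long (heavy) arm — producing the characteristic
*doublet*: a pair of peaks separated by a reagent-specific mass difference
(31.9721 Da for DSSO; 182.0071 Da for DSBSO). Instruments can be set up to
trigger MS3 scans on doublet peaks, producing spectra of each peptide in
linear form.

`xlms` implements the full search pipeline for such MS2-MS3 data: doublet
detection, MS3-to-doublet mapping, precursor mass correction, peptide
identification with a fragment-match scorer, multi-scan score boosting, and
two-step target-decoy validation, together with a synthetic benchmark
generator with known ground truth.

## Pipeline model and assumptions

For each MS2 spectrum the search proceeds as follows.

**Doublet detection.** All peak pairs are tested for the doublet spacing
`(delta + product_shift) / z` at each charge `z` up to `max_charge`
(default 4), where `delta` is the arm mass difference and `product_shift`
accounts for alternative cleavage products (e.g. water loss) the
cross-linker fragment may have undergone; only one product per arm is
enumerated, never stacked combinations. Accepted pairs must have a
light/heavy intensity ratio inside a configurable band (default 0.1-10, a
deliberately permissive stand-in for instrument-specific peak-quality
heuristics), arm-consistent deisotoped masses, and — when the MS1
precursor charge is declared — a plausible partner peptide mass under the
precursor-sum constraint. The peptide of the lowest-m/z doublet in a scan
is the alpha peptide, the others beta.

**Deisotoping and charge.** Charges are inferred from isotope envelopes
(spacing 1.00336/z, at least two consecutive members, capped intensity
growth); peaks without an envelope enumerate all charges up to the limit.
Doublet peaks are deisotoped by walking the envelope downward to the lowest
consistent member, because instruments frequently select a non-monoisotopic
peak for MS3.

**MS3 mapping.** An MS3 scan is assigned to a doublet peak when it was
recorded within `rt_window` minutes *after* its MS2 scan (one-sided window,
default 5 min), shares the MS2's MS1-level precursor m/z within the
precursor tolerance, and its own selected precursor matches the doublet
peak or one of its isotope envelope members. MS3 scans triggered on
co-isolated non-cross-linked peaks match no doublet and are excluded,
which is the main guard against false positives from stray MS3 spectra.
The corrected, cross-linker-free precursor mass of an assigned MS3 is the
deisotoped doublet mass minus the arm mass minus any product delta.

**Candidate search and scoring.** Proteins are digested in silico
(trypsin: cleave after K/R, not before P; 2 missed cleavages by default;
carbamidomethyl-C fixed). Candidates must match the corrected mass within
the precursor tolerance and carry an admissible link site: an internal
reactive residue — the C-terminal lysine of a tryptic peptide is excluded
unless the peptide is protein C-terminal, since a cross-linked lysine
resists tryptic cleavage — or position 1 of a protein N-terminal peptide.
Matches are scored with a binomial fragment-match score,
`-10 log10 P(X >= k)` with `n` theoretical b/y ions, `k` matched, and a
per-ion random-match probability estimated from the spectrum's peak
density and the fragment tolerance. The score is deterministic and
order-preserving in match quality; all downstream score propagation is
agnostic to the particular scorer. Besides the assigned MS3 scans, the MS2
spectrum itself is searched for each doublet's peptide (on by default),
and — when the precursor charge is known — for the *complementary*
peptide implied by the MS1 precursor mass, which recovers partners whose
own doublet went undetected.

**Pooling and boosting.** A peptide identified in several scans of the
same MS2 chain is more trustworthy. Scores for one peptide are pooled as

\[ \mathrm{boosted} = \max(\mathrm{scores}) \times (1 + p/100)^{\,n-1} \]

with `n` the number of distinct contributing MSn scans and `p` the boost
parameter: `p = 0` leaves the maximum unchanged and `p = 100` doubles it
for every additional scan; the default is `p = 20`. Pooling is keyed by
peptide and link site within a doublet pair, across arms, because MS2
evidence does not distinguish which arm a matched fragment series carried.

**CSM assembly and validation.** The two peptides of a scan are combined
into one cross-link spectrum match (CSM): combinations of doublet pairs
(and complementary-mass partners) are enumerated, those violating the MS1
precursor-sum check are dropped, and the best surviving combination —
largest min-score — is kept, one CSM per MS2 chain. The CSM score is the
smaller of the two peptide scores; CSMs of the same unordered peptide/site
pair are grouped into a cross-link whose score is the maximum over its
CSMs. Validation is two-step: target-decoy FDR at the CSM level, grouping,
then again at the cross-link level (1% each by default). Decoys are
whole-protein sequence reversals with a `REV_` accession prefix. The
estimator is `max(0, TD - DD) / TT`, treating decoy-decoy matches as an
estimate of the rate at which target-decoy matches arise by chance.
Thresholds are only placed at distinct score boundaries, so tied items are
accepted or rejected together and the reported estimate always describes
the actual accepted set; this makes the thresholding provably identical to
exhaustively scanning every achievable acceptance set.

Two post-hoc evaluation tools mirror common benchmark practice:
`validated_group_fdr()` computes the experimentally validated FDR of a
groupwise-synthesized library (the fraction of accepted cross-links
joining different groups or non-library peptides), and
`entrapment_filter()` trims the lowest-scoring cross-links until fewer
than a given fraction (default 1%) contain a peptide from spiked-in
entrapment proteins.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `prec_tol_ppm` | 10 ppm | precursor and doublet-mass matching |
| `frag_tol` / unit | 20 ppm | fragment matching; use 0.5 Da for ion-trap spectra |
| `max_charge` | 4 | charges enumerated when no envelope pins the state |
| `rt_window` | 5 min | one-sided MS3 mapping window |
| `boost_p` | 20 | multi-scan boost strength |
| `fdr_csm`, `fdr_crosslink` | 0.01 | two-step FDR targets |
| `prefilter_q` | 0.01 | linear-peptide prefilter q-value (`NA` disables) |
| `intensity_ratio_band` | 0.1-10 | doublet light/heavy intensity acceptance |

The tolerance defaults correspond to Orbitrap acquisition; they are
deliberately on the permissive end because the doublet-pair and
precursor-sum constraints do most of the specificity work.

## The synthetic benchmark

`make_library()` generates random tryptic-like peptides (length 6-20,
exactly one internal lysine as the link site, C-terminal K/R) partitioned
into groups of 6-10, mirroring the design of published synthetic
cross-linked peptide libraries in which peptides are cross-linked only
within their group, so any inter-group identification is a known false
positive. `simulate_run()` samples intra-group cross-links and emits, per
cross-link, one MS2 spectrum (both doublets with 3-member isotope
envelopes, sampled backbone fragments of both stub peptides, uniform
noise) and configurable MS3 spectra per doublet, plus optional
linear-peptide bait spectra and co-isolation artifact MS3 scans. Spectral
realism choices, made once and documented here: peak intensities are
log-normal; a fraction (default 0.7) of theoretical fragments is present;
m/z jitter is Gaussian with sigma = tolerance/3, using the precursor
tolerance for precursor-grade peaks (doublets, selections) and the
fragment tolerance for backbone ions; MS3 scans follow their MS2 within
(0, 2] minutes on a uniform retention-time gradient; MS3 precursors sit on
the +1 isotope with probability 0.3.

What the simulator does *not* model — chromatographic peak shapes,
deamidation and other open modifications, chimeric MS2 spectra beyond
simple co-isolation, inter-run variability, and realistic homology between
decoys and targets (reversed mini-proteins digest to peptides that rarely
co-elute in mass with targets, so decoy competition is weaker than in a
proteome-scale search). Passing the synthetic benchmark therefore
demonstrates the correctness of the algorithmic chain, not the
field-realistic FDR calibration of the scorer.

The shipped benchmark scale — a 30-peptide library, 20 sampled
cross-links, 2 MS3 scans per doublet, 30 noise peaks per spectrum, 20
simulation seeds for the FDR calibration check — was chosen to exercise
every code path (missed doublets, isotope-selected MS3 precursors,
complementary-mass recovery) while keeping a full run to a few seconds.

## Numerical and design choices

* Monoisotopic element and residue masses are embedded as constants;
  neutron spacing is approximated as 1.00336 Da and the proton as
  1.00728 Da, with all envelope arithmetic in neutral-mass space.
* DSSO arms are alkene `C3H2O` and thiol `C3H2OS`; DSBSO pairs the same
  alkene with a `C8H12O4S2` sulfoxide-core remnant, reproducing the
  182.0071 Da doublet spacing; intact added masses are `C6H6O3S`
  (158.0038 Da) and `C11H16O6S2` (308.0388 Da).
* When an MS3 precursor matches two doublet peaks within tolerance it is
  assigned to the closer one; exact ties go to the lower-m/z doublet.
* Degenerate inputs are values, not errors: empty spectra, empty candidate
  sets, and empty CSM lists propagate to empty (but well-formed) results;
  only malformed files and invalid cross-linker chemistry are fatal.
* An MS2-only run (no MS3 scans) proceeds with a warning, identifying both
  peptides from the MS2 spectrum alone.

## Worked example

```{r example, eval = FALSE}
lib <- make_library(30, group_size_range = c(6, 10), seed = 7)
sim <- simulate_run(lib, crosslinker("DSSO"),
                    sim_params(n_crosslinks = 20, ms3_per_doublet = 2),
                    seed = 11, out_dir = tempdir())

proteins <- read_fasta(sim$fasta_path)
spectra <- read_mzml(sim$mzml_path)
res <- run_search(spectra, proteins, run_config())
res

validated_group_fdr(res$accepted_crosslinks, as.list(lib$groups))
```

## Known limitations

* The fragment-match scorer is intentionally simple; it does not model
  intensity ranks, neutral losses, or immonium ions, and its absolute
  values are not comparable to commercial engine scores (the relative
  ordering, which is all the validation layer consumes, is).
* Only b/y ions are generated, so ETD/EThcD spectra (c/z ions) are not
  scored sensibly.
* Quantification, protein-protein-interaction-level FDR, and semi-tryptic
  digestion are out of scope.
* MGF input is rejected by design: the search requires MSn stage and
  precursor linkage, which MGF does not carry.
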