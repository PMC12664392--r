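---
title: "Profiling the specificity of peptide-centric T cell engagers with epiScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the specificity of peptide-centric T cell engagers with epiScan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiScan)
```

## The problem

T cell engagers that target an HLA class I / peptide complex see a composite
surface: the two HLA alpha-helices and the nine-residue peptide lying in the
groove between them. Because tens of thousands of distinct peptides are
presented by the same HLA allele, the central safety question for any such
binder is not affinity but *specificity*: which peptide variants still
activate T cells through the binder, and do any human self-peptides fall
inside that tolerance envelope?

epiScan implements the desk half of the standard experimental answer:

1. **Positional-scanning (X-scan) profiling.** Every position of the target
   peptide is substituted by the 19 alternative residues; pulsed target
   cells plus effector CD8+ T cells give a percent-activation readout per
   variant (e.g. % IFN-gamma positive cells). epiScan turns replicate
   matrices of these readouts into per-position *tolerance profiles*.
2. **Motif construction and proteome scanning.** Tolerance profiles
   serialize to PROSITE-style patterns which are scanned over a proteome
   FASTA to enumerate candidate cross-reactive self-peptides, the list that
   then goes back into cellular testing.
3. **Assay arithmetic.** The surrounding quantification: HTRF
   specificity-ratio hit calls, three-parameter dose-response fits with
   EC90 derivation, and chromium-release percent specific lysis.
4. **Structural footprints.** Buried interface areas, per-residue
   footprints, typed contacts and superposition RMSD on the binder/HLA
   complex, to connect functional tolerance with the physical interface.

## The profiling model

The activation matrix is a `position x residue x replicate` array on the
percent scale. The pipeline is deliberately minimal and order-fixed:

```
replicates --mean--> averaged matrix --scale--> normalized --threshold--> profile
```

* **Averaging before normalization.** Replicates are averaged cell-wise
  first, and the averaged matrix is normalized to its own wild-type cells.
  Normalizing each replicate first and then averaging gives slightly
  different weights when wild-type cells vary between replicates; the
  package fixes the documented order (per-replicate normalization remains
  available by calling `normalizeToWildType()` on the multi-replicate
  object). Missing cells are *errors*, never imputed zeros — a silently
  imputed zero would shrink tolerance sets without any trace.
* **Per-position anchoring.** Each position is normalized to 100% at its
  own wild-type cell. After normalization the wild-type cell is set to
  exactly 100, so the wild-type residue is a member of every tolerance set
  by construction, not by special-casing. Values above 100% (variants more
  stimulatory than wild type) are legal and preserved.
* **Strict threshold.** A residue is tolerated when its normalized
  activation *exceeds* the threshold; the default of 30% is the
  conventional cutoff for "substantial" T cell activation in this assay
  family. The strict inequality matters only for values exactly at the
  cutoff, but fixing it keeps threshold-sweep behaviour monotone: raising
  the threshold can only shrink the sets.
* **Anchor positions.** In the X-scan all nine positions are individually
  substituted. In the alanine scan the two MHC anchor positions (p2/p9 for
  HLA-A*02:01 9-mers) are mutated jointly, because single anchor mutants
  mostly report on MHC binding rather than binder recognition; the joint
  variant is carried as one pseudo-position (`"2+9"`) in
  `alanineSensitivity()`.

## Motifs and proteome scanning

Tolerance sets serialize to the ScanProSite convention: multi-residue
classes as alphabetically sorted brackets, singletons bare, positions joined
by dashes. Emission is deterministic and byte-stable, and
`parseMotif(emitMotif(m))` is the identity — the pattern string is treated
as an exchange format, not a display string.

Scanning is implemented with a regular-expression lookahead (so overlapping
windows are all reported) and checked in the test suite against a naive
per-window set-membership enumeration, which is the semantic definition.
Conventions:

* Offsets are 1-based inclusive.
* Non-canonical letters (X, B, Z, U, `*`) fail every class. They are never
  expanded into ambiguity sets; expanding them would inflate the candidate
  list with sequences that do not exist as such.
* The deduplication key of the candidate summary is the peptide string; a
  peptide occurring in many proteins is one candidate with provenance.
* `crossReactivityCandidates()` removes each profile's own wild-type
  epitope from the summary by default: the scan looks for *non-self*
  look-alikes, and the index epitope trivially matches its own motif.
* No MHC binding-affinity filter is applied to candidates. None is part of
  the method being modelled; if desired, predicted binding can be applied
  downstream on the summary table.

## Assay arithmetic

* **HTRF specificity.** The ratio is the target-complex signal over the
  *worst* (largest) negative-control signal — the conservative reading when
  several negative controls are run. The hit call is inclusive
  (`ratio >= fold`), with presets at 25-fold (screening) and 50-fold
  (stringent); neither is silently preferred. Non-positive control signals
  are floored at the smallest positive observed signal times 1e-3 before
  division, so a zero control cannot manufacture an infinite ratio.
* **Dose-response.** The three-parameter log(agonist) model fixes the Hill
  slope at 1: `response = bottom + (top - bottom) / (1 + EC50/dose)`.
  Fitting is Levenberg-Marquardt least squares (minpack.lm) on
  `log10(EC50)` with a fixed, deterministic initialization (bottom = min
  response, top = max response, EC50 = dose nearest half-maximum) and
  bounds three decades beyond the tested dose range. Constant responses are
  rejected rather than returned as a flagged flat fit, preserving the
  invariant `EC50 > 0`. Under unit slope the effective concentration at
  F% of span has the closed form `EC_F = EC50 * F/(100-F)`; EC90 is
  therefore exactly nine times EC50, which the tests assert to machine
  precision.
* **Specific lysis.** The chromium-release formula is applied exactly;
  values outside [0, 100]% are legal (counting noise around the plateaus)
  and reported as-is with a warning rather than clamped.

## Structural footprints

* **SASA** is Shrake-Rupley with a 1.4 Angstrom probe, 960 deterministic
  golden-spiral quadrature points per atom, and a NACCESS-like heavy-atom
  radius set (C 1.70, N 1.55, O 1.52, S 1.80). 960 points put the
  quadrature error on analytic spheres and two-sphere cap systems well
  under 1-2%, which the tests verify; doubling the points moves totals by
  less than 0.5%.
* **Interface area** follows the PISA convention: half the SASA lost upon
  complexation, with each side computed in isolation at unchanged
  coordinates. Per-residue buried areas are clipped at zero (tiny negative
  quadrature noise); the clip is applied after residue aggregation, so the
  two-sided per-residue sum still reproduces twice the interface area to
  well under a percent.
* **Contacts** are distance-only: hydrogen bonds as donor/acceptor-typed
  N/O pairs at <= 3.5 Angstrom (typing from a fixed per-residue atom
  table), hydrophobic contacts as pairs of apolar carbons (carbons bonded
  only to C/H in standard topologies) at <= 4.5 Angstrom. Angle terms would
  require placed hydrogens, which ~3 Angstrom maps do not support.
* **Alternate locations** keep the highest-occupancy conformer; waters and
  hetero records are excluded from SASA and contacts by default.
* **Superposition** is the Kabsch least-squares alignment with the proper
  rotation enforced (a reflection-only optimum is corrected via the sign of
  the smallest singular vector). Atoms pair by author residue number after
  dropping residues unmodelled on either side; the default pairs C-alpha
  atoms only, with all-atom pairing as an option, since reported overall
  RMSD values in this regime are conventionally C-alpha based.

The deposited complexes this module is aimed at are not shipped with the
package (coordinate files are obtained from the PDB); all algorithmic
behaviour is validated on toy structures with closed-form answers, and the
structure-anchored check in the test suite documents the expected values
for the deposited models when the files are supplied locally.

## The simulators, and what passing tests show

`simXScan()` draws tolerated cells from Normal(80, 5) and non-tolerated
cells from Normal(5, 5) percent (clipped at zero), two replicates — levels
chosen to mirror a strong-agonist assay where tolerated variants sit near
wild-type activation and non-tolerated ones near background. A guard
enforces a gap of more than four noise SDs between the levels, so the
designed profile is recoverable at the 30% threshold with margin; the test
suite measures a recovery rate of at least 99% over 500 seeded runs.
`simProteome()` plants motif-matching peptides at recorded offsets in
random background (uniform residue usage by default; SwissProt-like
frequencies via `uniprotResidueFreqs`). `simDoseResponse()` adds Gaussian
noise to exact model curves. `toyStructure()` builds the analytic SASA
fixtures and a minimal two-strand hydrophobic interface.

What the simulators do *not* emulate: plate effects and position-correlated
assay noise, above-wild-type activation tails, proteome composition biases
beyond residue frequencies, and real side-chain packing. Passing tests
therefore demonstrate correctness of the arithmetic and the scanning
semantics under clean separability — not that a 30% threshold is the right
biological cutoff for any particular binder, which remains an experimental
question.

Problem sizes in the default test run are kept modest (matrices of
9 x 20 x 2; proteomes of 10-50 proteins of 120-300 residues; 100 proteomes
in the scanner-equivalence property; 500 seeds in the recovery property;
toy structures of 1-30 atoms) — large enough to exercise every code path
and the documented tolerances while keeping the suite fast.

## Worked example

```{r pipeline}
ny1_pattern <- paste0("[ACFGHILMNQRSTVWY]-[ACILMQV]-[ACDFGHILMNPQSTVW]-",
                      "[FILMT]-W-[FILMV]-[CFILMQRSTVY]-[QT]-[ACITV]")
truth <- ToleranceProfile("SLLMWITQV", motifClasses(parseMotif(ny1_pattern)))
sim <- simXScan(truth, seed = 1)
profile <- toleranceProfile(normalizeToWildType(averageReplicates(sim$matrix)))
emitMotif(asMotif(profile, id = "NY_1"))
```

```{r scan}
proteome <- simProteome(nProteins = 30, proteinLength = 300,
                        planted = c("SLLMWLTPL", "SLLMWITQV"), seed = 2)
ny2_pattern <- paste0("[ACFHIMNPQRSTVWY]-[FILMVW]-[ILMQV]-[IM]-W-[FILMPVW]-",
                      "[ACFGILMNQRSTV]-[ACDEFGHKLMNPQRSTVWY]-[ACFGILSTV]")
hits <- scanProteome(proteome$records, parseMotif(ny2_pattern, id = "NY_2"),
                     exclude = "SLLMWITQV")
hits$summary
```

```{r assay}
d <- 10^seq(-11, -7, by = 0.5)
fit <- fitDoseResponse(d, doseResponseModel(d, 0, 100, 1e-9))
coef(fit)
effectiveConcentration(fit, 90)
specificLysis(400, 100, 500)
```

```{r structure}
s <- toyStructure("mini_interface")
report <- analyzeInterface(s, "A", "B")
report
```

## Known limitations

* Tolerance calls are per-position and independent; epistasis between
  peptide positions (a substitution tolerated only in combination) is
  outside the single-substitution design the X-scan itself uses.
* Contact typing is distance-only and residue-table driven; modified
  residues and ligands are not typed.
* The dose-response module fits one curve at a time; statistical comparison
  between curves (shared-parameter fits, F-tests) is out of scope.
* Proteome scanning takes the FASTA the user supplies; taxonomy filtering,
  isoform collapsing and database retrieval are upstream concerns.
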