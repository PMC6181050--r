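---
title: "Methods: cross-link identification, topology and gel stoichiometry in xlscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-link identification, topology and gel stoichiometry in xlscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlscout)
```

xlscout identifies chemically cross-linked peptide pairs from tandem mass
spectra, turns them into subunit adjacency and distance restraints, and
quantifies subunit stoichiometry from uniformly ¹⁴C-labeled gel
densitometry. This vignette explains the models behind each pipeline, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not demonstrate.

## The cross-link search model

### Chemistry

DSS (disuccinimidyl suberate) is a homobifunctional NHS ester that couples
primary amines: lysine side chains and the protein N terminus. The intact
bridge left between two coupled peptides is the suberate residual, C8H10O2,
monoisotopic mass 138.06808 Da. The isotope-coded reagent is an equimolar
d0/d12 mixture; the heavy form carries twelve deuteriums, so its bridge is
heavier by 12 × (m(D) − m(H)) = 12.07532 Da. `cross_linker("DSS")` encodes
exactly this arithmetic, and every heavy-form quantity in the package is
derived from it rather than stored separately.

Attachment-site rules (`link_sites()`): an internal lysine is a valid site;
a peptide's C-terminal lysine is not, because a lysine carrying the linker
would have blocked the tryptic cleavage that produced that terminus. The
single exception is the protein's own C-terminal residue, where no cleavage
was needed — we allow it and the search output flags such sites. Position 1
of the protein N-terminal peptide is a site through the α-amine. Mono-links
(hydrolyzed, single-ended linker) and intra-peptide loop-links are not
searched; both are extension points rather than scored hypothesis classes.

### Digestion and the peptide index

Trypsin cleaves after K/R except before proline. Cross-linked lysines
suppress cleavage, so the search defaults to `max_missed = 3` missed
cleavages (configurable), with peptide lengths 4–60. Isoleucine and leucine
are distinct letters with equal mass; reported sequences keep the database
letter. Input sequences are taken as already-mature proteins — no transit
peptide or initiator-methionine logic is applied, because carbon counting
and mass arithmetic must refer to the mature chain actually present in the
complex. Methionine oxidation (+15.994915 Da) is the only variable
modification; the index holds one singly-oxidized variant per methionine.

### Scoring

MS2 spectra are deconvoluted to neutral fragment masses
(M = z·m/z − z·1.00727646 Da) at every plausible fragment charge up to
`precursor_charge − 1`, merging hypotheses within 0.01 Da (keeping the
most intense representative — the simplest deterministic rule) and capping
at the precursor neutral mass. Working in neutral-mass space means
theoretical fragments are computed once, not per charge state.

For a candidate pair (α, β) with linked positions (a, b), the theoretical
ions are b₁..b_{n−1} and y₁..y_{n−1} of each peptide; an ion spanning the
linked residue gains the bridge plus the *intact partner peptide* mass.
Matching uses a dual tolerance — a peak matches within 0.05 Da *or* 10 ppm,
whichever is wider at that mass — and each ion and each peak is used at
most once. Because both lists are sorted and tolerance windows are
intervals whose endpoints increase with mass, the sweep that assigns each
successive ion the smallest unused peak in its window attains the true
maximum bipartite matching (verified against an exhaustive oracle in the
tests).

The match count is scored with a Poisson survival model: under the null
that observed peaks fall at random, the number of matched ions among N
theoretical ions is ≈ Poisson(μ) with μ = N·p. The per-ion probability p is
estimated from constant peak density: p = (peak count × 2 × effective Da
tolerance) / (scored mass range, taken as precursor mass − 100 Da). The
p-value is P[Pois(μ) ≥ n], and the E-value multiplies by the number of
candidates scored for the spectrum. The survival form makes the score
monotone in the match count at fixed μ, and the E-value is calibrated on
pure-noise simulations (the fraction of noise spectra reaching E ≤ t stays
within a small constant factor of t).

### Two-step validation

Step 1 scores each spectrum against candidates from a small targeted
database and keeps the best hit if E ≤ `e_max` (default 0.01; this
threshold is a package choice and fully configurable). Step 2 re-scores
the spectrum against the whole proteome — all cross-link pairs *plus
linear peptides at the same precursor mass* — and the step-1 hit is
reported only if it remains top-ranked. This "survives as top hit"
criterion is the package's reading of the two-step strategy; an
alternative mode (`validate_mode = "factor"`) accepts hits within a
configurable E-value factor of the whole-proteome best, for users who
prefer a softer criterion. When light/heavy precursor pairing links two
scans to the same winning candidate in both isotope forms, the
identification is upgraded to `paired` evidence; pairing is a bonus flag,
not a hard filter, since how the original acquisitions were combined is
an acquisition-design question, not a scoring one.

No decoy-FDR layer is applied by default — validation is the two-step
competition itself — but reversed-sequence decoys can be simulated for
calibration studies.

### Key parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `precursor_ppm` | 10 | ppm | high-accuracy Orbitrap-class precursor tolerance |
| `frag_da` / `frag_ppm` | 0.05 / 10 | Da / ppm | dual product-ion tolerance, match within either |
| `e_max` | 0.01 | — | step-1 acceptance; configurable |
| `max_missed` | 3 | — | linked K suppresses cleavage |
| `max_precursor_charge` | 6 | — | acquisition-side charge ceiling |
| `max_fragment_charge` | precursor − 1 | — | standard practice |
| `restraint_threshold` | 30 | Å | DSS Cα–Cα reach |

## Topology and distance restraints

Cross-link records become a hypergraph with one hyperedge per product;
products joining three subunits stay single hyperedges and are expanded to
*flagged* pairs only on projection, because a three-membered product does
not prove each pairwise contact. The packaged table of 22 curated PSI-LHCI
cross-linked products (one of which is a triple) spans all nine LHCA
subunits and ten PSI core subunits.

Peptides are placed on structure chains by exact substring match first,
then by the best gapless sliding alignment at ≥ 60% identity; equally good
placements raise an ambiguity error rather than a silent choice. Cα–Cα
distances are Euclidean; a restraint is satisfied at ≤ 30 Å, and the
26–30 Å range is reported as a near-limit flag rather than a second
cutoff. Structure input covers PDB and mmCIF polymer Cα records;
chain-to-subunit correspondence is a user-supplied table, since mapping an
algal complex onto a vascular-plant structure is inherently a manual,
cross-species judgement. Homology modeling and rigid-body placement of
unmapped subunits are out of scope; externally produced model coordinates
are accepted as input.

## Gel stoichiometry

With uniform ¹⁴C labeling, every carbon contributes equally to a band's
autoradiographic signal, so signal ∝ copies × carbon number, and
signal ÷ carbons is a relative molar amount. Three gel systems are
combined:

1. **Reference system** (high-molarity-Tris, 55 °C): resolves LHCA4, LHCA6,
   LHCA3, LHCA5, PSAD and PSAF as single bands; abundances are molar
   values normalized to PSAF.
2. **Calibrated system** (same chemistry, 6 °C): resolves LHCA1, LHCA9 (and
   LHCA4, LHCA8), but its overall gain is unknown. The PSAD+PSAF band,
   whose members were measured separately in the reference system, fixes
   the gain: the band's molar value — its signal divided by the
   abundance-weighted mean carbon number of its members — must equal the
   sum of the reference abundances (1.17 + 1.00 = 2.17). The
   abundance-weighted effective carbon number matters: dividing by the
   plain carbon sum would only be correct for equimolar members.
3. **2D partition**: LHCA2, LHCA7 and LHCA8 never run alone in the
   reference system; their two composite bands are summed and split by the
   2D spot-signal fractions, then each share is carbon-normalized. The
   order — split the *signal* first, then divide by carbons — is the one
   consistent with signal ∝ copies × carbons (a composite band's raw
   signal is carbon-weighted); splitting carbon-normalized totals by
   carbon-normalized fractions is algebraically identical, and the
   package exposes both formulations. Because only fractions enter, the
   2D system's gain cancels without calibration.

When a subunit appears in several bands of one system (LHCA2 splits
between the LHCA7/2 and LHCA8/2 bands), only the bands' sum is used, so
the unknown split fraction never enters.

Replicates are summarized as mean and standard error (sample sd / √n,
n = 3 by default). Copy numbers are means rounded to the nearest integer
(ties away from zero); means whose fractional part falls in [0.4, 0.6]
trigger an explicit ambiguity warning rather than a silent decision. The
reference subunit (PSAF) is identically 1 by construction.

## The synthetic-data generator

The generator provides the statistical structure the pipelines assume,
with known truth:

- **Proteomes**: uniform residue frequencies, ≥ 2 internal lysines per
  protein, lengths 80–120 (search tests) or 150–250 (stoichiometry tests,
  matching small membrane-protein mature chains).
- **Spectra**: planted cross-links receive a light (and optionally heavy,
  +12.07532 Da) spectrum; theoretical fragments are subsampled at a set
  fraction, perturbed with Gaussian ppm error, emitted at charges 1–2
  under precursor charges 3–6, and mixed with uniform noise peaks over
  [100 Da, precursor mass] with exponential intensities — the simplest
  null consistent with the constant-density E-value model. Pure-noise
  spectra reuse real candidate precursor masses so the search has
  something to score.
- **Gels**: band signal = system gain × Σ members (copies × carbons),
  log-normal multiplicative noise of chosen CV, random per-system gains
  (log-uniform in [0.5, 2]) so tests prove gain invariance. Default copy
  numbers are the measured PSI-LHCI values (LHCA1 1.81, other LHCAs 1,
  PSAD 1.17, PSAF 1).

All generators are pure functions of (parameters, seed) and restore the
caller's RNG state.

What the simulations do **not** emulate: isotope envelopes and centroiding
artifacts, retention-time structure (RT is a fixed spacing), intensity
models of real fragmentation, acid-labile or semi-tryptic cleavage,
homologous/paralogous sequence families (random sequences are far more
distinguishable than LHCA paralogs), or gel-lane detection. Passing tests
therefore demonstrate correctness of the arithmetic and the selection
logic under the stated noise model, not instrument-grade performance on
real thylakoid data.

### Problem sizes

The standard recovery study plants 50 cross-links among 10 targeted
proteins and validates against those 10 plus 50 decoy proteins, with
fragment coverage 0.8, 5 ppm mass error and 10 noise peaks per spectrum;
false-validation checks use 30 pure-noise spectra. These sizes give stable
rates (≥ 90% validation, zero noise validations across seeds) while
keeping the whole suite and the acceptance script fast on a single CPU.

## Numerical and reproducibility choices

- Residue and constant masses are fixed at standard monoisotopic precision
  (≥ 5 decimals); all tolerances are explicit function arguments.
- Ties in candidate ranking break by matched-ion count, then
  lexicographically by (protein, start) — never by memory order.
- Deconvolution merges keep the most intense representative;
  equal-intensity ties keep the lower mass.
- Report files carry `#` provenance headers with the package version and
  the full resolved configuration, but no timestamps: identical inputs and
  configuration must produce byte-identical files, and the test suite
  checks this by md5.
- Degenerate inputs fail loudly: empty databases, bands with non-positive
  carbon counts, subunits without a resolution route, missing Cα atoms and
  ambiguous peptide placements are all named errors.

## Known limitations

- The per-ion null probability assumes constant peak density; structured
  noise (e.g. unfragmented precursor series) would make E-values
  optimistic.
- The first listed attachment site of each peptide is used for fragment
  generation; site-level localization among several lysines in one peptide
  is not scored.
- mmCIF reading covers polymer Cα records through bio3d; exotic entries
  (multi-model ensembles, insertion codes) are untested.
- The stoichiometry resolver supports one calibrated system and one
  partition system per run — the documented three-system design — not
  arbitrary band-sharing topologies.
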