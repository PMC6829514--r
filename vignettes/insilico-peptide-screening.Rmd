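---
title: "In-silico screening of bioactive peptides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico screening of bioactive peptides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

`pepscreen` models the computational half of a bioactive-peptide discovery
campaign: given protein sequences and a catalogue of short peptides with
known ACE-inhibitory, DPP-IV-inhibitory or other activities, which protease
would theoretically release the most bioactive peptides, and do the
in-vitro assay numbers back that up? This vignette documents the models,
the tunable parameters, the numerical and design choices, and what the
synthetic-data tests do and do not demonstrate.

## The cleavage model

Proteolysis is modelled per peptide bond. Site $i$ is the bond between
residues $i$ and $i+1$ of the substrate; in Schechter–Berger notation the
residues around the scissile bond are P2 ($i-1$), P1 ($i$) and P1$'$
($i+1$). A `cleavage_rule` fires at site $i$ iff

$$\bigl(\mathrm{P1} \in \text{p1\_allow} \;\lor\; \mathrm{P2} \in
\text{p2\_allow}\bigr) \;\land\; \mathrm{P1} \notin \text{p1\_block}
\;\land\; \bigl(\text{p1prime\_allow} = \varnothing \lor \mathrm{P1}'
\in \text{p1prime\_allow}\bigr) \;\land\; \mathrm{P1}' \notin
\text{p1prime\_block}$$

and an enzyme cuts wherever any of its rules fires. Firing is per-bond and
independent, so no tie-breaking is needed and site enumeration is
deterministic. Allow and block sets for the same position must be
disjoint (checked at construction).

Digestion is *complete* by default: every fireable site is cut, and the
resulting fragments partition the parent (their concatenation restores the
sequence — a tested invariant). Missed cleavages exist only for the
MS-support use case: with `max_missed = m`, every run of at most $m+1$
consecutive zero-missed fragments is additionally emitted with its
`n_missed` count, matching how search engines enumerate tryptic peptides
(typically $m = 2$). Partial/kinetic digestion is deliberately out of
scope: the in-vitro degree of hydrolysis of a real 4-hour digest plateaus
around 18–22 %, and no attempt is made to emulate that partiality.

### The bundled rule table and its confidence

Protease specificity is almost always published as prose, not as machine
rules, so the bundled registry is an explicit editorial choice in the
Keil / PeptideCutter tradition, versioned as `RULESET_VERSION` and stamped
into every report so results are reproducible against a declared table
rather than a remote service:

| enzyme | EC | rule | confidence |
|---|---|---|---|
| pepsin_ph_gt2 | 3.4.23.1 | P1 ∈ {F, L, W, Y, E}, block P1′ = P | high |
| trypsin | 3.4.21.4 | P1 ∈ {K, R}, block P1′ = P | high |
| chymotrypsin_a | 3.4.21.1 | P1 ∈ {F, Y, W}, block P1′ = P | high |
| lys_c | 3.4.21.50 | P1 = K | high |
| papain | 3.4.22.2 | P1 ∈ {R, K} or P2 = F, block P1′ = P | medium |
| bromelain_stem | 3.4.22.32 | P1 ∈ {K, R, A, Y, G}, block P1′ = P | low |

Pepsin's documented refusal to cut at V, A or G is honoured implicitly —
those residues are simply absent from its allow set — rather than as a
block list, keeping allow/block disjointness trivial. Stem bromelain's
protein-substrate specificity is poorly characterised (its best-described
preference is for small synthetic substrates), so that entry is flagged
lowest-confidence and, like every default, can be overridden by name
through `parse_enzyme_config()`'s YAML schema.

## Catalogue matching

Two matching semantics coexist, and distinguishing them is the main
interpretive choice in this kind of screening:

* **Profile** (`profile_protein`): every occurrence of every catalogue
  peptide as a substring, with 1-based inclusive coordinates. Counts are
  *occurrence* counts — overlapping and repeated occurrences each count,
  and a multi-activity peptide contributes one count per annotation. This
  is what makes published per-protein totals run into the hundreds or
  thousands; a `distinct = TRUE` mode counts unique peptides instead.
  `frequency_of_occurrence()` divides by residue count (the classic "A"
  parameter, reported to 4 decimals).
* **Active fragments** (`active_fragments`): a digest's released peptides
  are looked up *whole*. A released 10-mer that merely contains "AE" is
  not a hit. Whether repeated releases count once or per instance is not
  standardised; both modes are provided, instance counting is the default,
  and reports label the mode.

Matching is exact, case-normalised and direction-sensitive — "AE" is a
DPP-IV-inhibitory dipeptide while its reversal "EA" is an ACE inhibitor,
so reversal symmetry must never be assumed. Ambiguity codes (B, J, O, U,
X, Z) are rejected at validation rather than silently mapped, because
cleavage rules and matching are defined only on the canonical 20 residues
and silent substitution would corrupt counts.

The bundled catalogue (`demo_catalogue_path()`, ~150 entries) is a
synthetic demo table of literature-typical di-/tri-peptides assembled for
tests and examples. It is *not* a copy of BIOPEP-UWM or any hosted
database: those are versioned, and absolute hit counts depend on the
database snapshot, which is why published absolute totals are not treated
as reproduction targets here. The "other activities" grouping used by
`rank_enzymes` (everything outside ACE/DPP-IV inhibition, configurable)
mirrors the usual screening-figure convention.

## Mass and assay arithmetic

Peptide masses use residue constants pinned to 6 decimals
(`AA_MONO_MASS`, `AA_AVG_MASS`, water 18.010565 Da, proton 1.007276 Da):
published 2-decimal masses are only reproducible to the last digit if the
constants are fixed, so they are part of the package's versioned surface.
$m/z(z) = (M + z \cdot 1.007276)/z$. Additivity
($M_{AB} = M_A + M_B - M_{H_2O}$) and the charge identity are tested on
random peptides to $10^{-9}$ relative tolerance. No b/y fragment-ion
annotation or probabilistic identification scoring is attempted.

The assay formulas are linear in their numerator inputs and pinned at the
boundaries (0 % when sample equals control, 100 % at complete inhibition or
hydrolysis). Degenerate denominators (total = baseline amino groups, zero
control slope, equal positive/negative controls) are errors; *negative*
computed inhibition — a sample slope exceeding the control — is returned
unclamped with a warning, because clamping would hide assay problems.
OPA quantification fits an unweighted least-squares line (weighting
schemes are out of scope), reports $R^2$, and flags extrapolation beyond
the standard range instead of refusing it.

## Synthetic data: what it emulates, and what it does not

The generators make every stage testable without downloads:

* `random_proteins()` draws i.i.d. residues from a composition (default
  uniform over 20; lengths uniform in a range). Defaults of 100–300
  residues place the synthetic substrates in the size range of typical
  muscle-protein screening targets while keeping brute-force oracles
  cheap. An `exclude` argument rejection-samples sequences so a planted
  motif cannot also occur by chance, which is what makes exact-count
  recovery assertions meaningful.
* `plant_releasable()` inserts a motif between flanks chosen from the
  enzyme's P1 allow set (respecting P1′ constraints) so a complete digest
  releases the motif intact. Two preconditions are enforced with errors:
  the motif must contain no internal cleavage site, and its *last* residue
  must itself fire the P1 rule — the C-terminal boundary cut cannot come
  from a flank. The construction is verified by actually digesting the
  modified protein, so local context interference is caught rather than
  assumed away.
* `synthetic_assay()` generates readouts whose noiseless evaluation
  returns the target inhibition exactly. The ACE branch simulates the
  30-minute kinetic read (control slope −0.010 absorbance/min, per-read
  Gaussian noise of sd `noise_sd`, slope re-fit by least squares); the
  DPP-IV branch perturbs the four endpoint absorbances (blank 0.05,
  positive control 1.05, negative control 0.05) with the same noise. A
  single `noise_sd` thus propagates coherently to both assays. The default
  truth values used in examples (≈78 % ACE, ≈44 % DPP-IV at 2 mg/mL)
  echo the scale of a strong pepsin hydrolysate.

Randomness policy: every generator seeds R's Mersenne-Twister from the
caller's seed plus a fixed per-operation offset inside a local RNG scope,
so operations have independent substreams (adding one never perturbs
another's draws), runs are bit-reproducible given the seed, and the
caller's global RNG state is untouched.

What passing these tests shows — and does not. The synthetic proteins have
i.i.d. residues; real proteomes have repeats, biased composition, domains
and post-translational modifications, none of which is emulated. The
end-to-end recovery property (planting $k$ copies of a pepsin-releasable
motif yields ≥ $k$ active-fragment hits and ranks pepsin first against
bromelain and papain) validates the *pipeline logic*, not any biological
claim about a particular proteome; with a real catalogue the analogous
qualitative ordering is an empirical result that depends on the catalogue
version and the input sequences.

## Verification strategy and problem sizes

Every load-bearing computation has an independent oracle in the test
suite: cleavage sites against a per-bond brute-force evaluation of the
rule semantics (all six bundled enzymes, random sequences up to 200
residues); missed-cleavage enumeration against direct enumeration over all
substrings (≤ 8 sites); profiling against an all-substrings scan (200
random protein/catalogue pairs, proteins to 150–300 residues, catalogues
to 50 entries); the partition invariant on 1000 random proteins; assay
recovery by Monte Carlo at 1000 replicates (mean within 3 standard
errors). These sizes keep the whole suite under half a minute while giving
the properties enough room to fail if the engine were wrong.

## Known limitations

* No kinetic or partial digestion, no pH-dependence beyond distinct named
  enzymes, no exopeptidase trimming.
* Whole-fragment matching means a catalogue peptide buried inside a large
  released fragment is invisible to `active_fragments` (by design; use
  `profile_protein` for substring semantics).
* The bromelain default rule is low-confidence (see above).
* No IC50 / quantitative-activity modelling, no fuzzy or homology
  matching, no MS/MS spectrum simulation or scoring.
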