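---
title: "Quantitative crosslinking MS with isobaric Qlinker reporter ions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative crosslinking MS with isobaric Qlinker reporter ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(QlinkerQuant)
```

# The measurement model

Quantitative crosslinking mass spectrometry (qCLMS) compares the
abundance of crosslinker-modified peptides between two states of a
protein or complex. With a 2-plex isobaric, amine-reactive crosslinker
("Qlinker"), the two samples are crosslinked separately with the two
reagent isotopologs, combined immediately afterwards, co-digested and
measured together. The two reagents have identical intact mass, so each
modified peptide appears as a single precursor; fragmentation releases
channel-specific reporter ions whose intensities encode the relative
abundance of the peptide in the two samples.

The reporter moiety is the 1-imino-2,6-dimethylpiperidin-1-ium cation.
The 126 channel is the all-^12^C cation C~8~H~16~N^+^; in the 127
channel one carbon is ^13^C. As intrinsic cations their m/z at charge 1
is the composition mass minus one electron mass:

* channel 126: `r sprintf("%.6f", reporterMz()[["126"]])`
* channel 127: `r sprintf("%.6f", reporterMz()[["127"]])`

These masses sit between the b1^+^/immonium region and the first
isotope cluster of common fragments: leucine/isoleucine b1^+^ ions fall
at 114.09, asparagine at 115.05 and aspartate at 116.03, comfortably
below the reporter windows. All mass arithmetic in the package is
derived from elemental compositions and IUPAC monoisotopic atomic
masses hard-coded to at least seven decimals (`massConstantsTable()`
exports the full set); every m/z is routed through `ionMz()`, which
makes the proton (1.007276466621 Da) and electron (0.000548579909 Da)
conventions explicit.

The mass added across a crosslinked lysine pair is the labeled diacid
C~15~H~26~N~2~O~5~ (one ^13^C) minus two waters:
`r sprintf("%.4f", qlinkerDeltas()["crosslink", "deltaMass"])` Da. A
monolink (one arm hydrolyzed) adds one water more:
`r sprintf("%.4f", qlinkerDeltas()["monolink", "deltaMass"])` Da. The
difference is pinned to the water mass by hydrolysis stoichiometry and
is verified as an invariant in the tests.

# Reporter extraction and impurity correction

For every identified MS2 spectrum the raw channel intensities
$I_{126}, I_{127}$ are the sums of peak intensities within a symmetric
window (default 0.005 Da, roughly 40 ppm at these masses) around the
theoretical reporter m/z. Summation rather than the maximum is the
default because centroiding occasionally splits a reporter peak; the
maximum is available via `method = "max"`.

Because the ^13^C reagent is about 99% pure and natural isotopes
contribute to the heavier channel, the observed intensities are a mixed
version of the true ones. With the purity matrix $M$ (column $j$ = the
fractional distribution of channel $j$'s true signal across observed
channels; package default `defaultPurityMatrix()`),

$$ M \begin{pmatrix} A_{126} \\ A_{127} \end{pmatrix} =
   \begin{pmatrix} I_{126} \\ I_{127} \end{pmatrix}, \qquad
   M = \begin{pmatrix} 0.90754 & 0.01 \\ 0.09246 & 0.90724 \end{pmatrix}. $$

`correctImpurity()` solves this system; `impurityCoefficients()` gives
the equivalent closed forms obtained by eliminating one channel,
$A_{126} = (I_{126} - 0.01102\,I_{127})/0.906521$ and
$A_{127} = (I_{127} - 0.10188\,I_{126})/0.906221$, which serve as an
independent cross-check in the test-suite. The matrix is configurable
per reagent lot and treated as opaque calibration data.

Two numerical choices matter here. First, corrected intensities that
come out non-positive (or at float-zero, below a relative guard of
1e-9) are *flagged* and excluded from ratios rather than clamped to
zero - clamping would fabricate infinite ratios. Second, the log2 ratio
is defined only when both corrected channels are strictly positive and
is never ±Inf.

# Site-level aggregation and conventions

Each quantified spectrum contributes one log2 ratio to its site: a
single `(protein, residue)` for monolinks, an unordered residue pair
for crosslinks, stored canonically (lexicographic by protein, then
residue) so that swapping the alpha/beta peptides cannot split a site.
The site summary is the unweighted arithmetic mean of the per-spectrum
log2 ratios, with SD and spectrum count; intralinks and interlinks are
distinguished by protein identity.

Two orientation conventions coexist in practice and both are supported:
mixing-series and null analyses conventionally use log2(127/126), while
label-swap comparisons use log2(126/127). Every quantification function
takes an `orientation` argument; swapping the labels and negating the
orientation leaves |log2 ratio| unchanged (a tested property).

`recenterSites()` shifts a selected group of sites so that its median
(or mean) sits at a target value, leaving all other sites untouched and
recording the applied shift. This is the operation used when one
protein is deliberately present at a different molarity in one channel
- the expected offset is removed before comparing distributions.

# Study-level analyses

* `evaluateMixing()` regresses observed on expected log2 ratios over a
  known mixing design (default levels 10:1, 5:1, 1:1, 1:5, 1:10) by
  unweighted OLS. Accurate quantification shows a slope near 1; a
  nonzero intercept indicates a global channel bias introduced before
  mixing.
* `swapJoin()` outer-joins the site tables of two label-swapped
  experiments; only sites quantified in both are regressed (OLS), where
  a genuine swap shows anti-correlation (slope near -1).
* `classifyChanges()` calls a site *changed* only when |log2 ratio|
  reaches log2(fold) (default fold 2) in **both** experiments with
  opposite signs; same-sign exceedances are *inconsistent*, and sites
  seen in one experiment are never called changed (they are flagged
  when their single ratio is large). The direction requirement is made
  explicit here; it is what the four quadrants of a swap scatter plot
  encode implicitly.
* `ratioDistributionSummary()` reports the fraction of sites within a
  ±0.5 log2 window (per link class), the summary used for null
  experiments where no conformational change is expected.
* `interferenceScan()` counts spectra carrying any peak within a ppm
  window (default 40) of the reporter masses, quantifying how often
  fragment ions of unlabeled peptides would contaminate the reporter
  windows.

# Spectrum validation

Identified spectra can be screened with the rule used for manual
evaluation of crosslink spectra: the match passes when every peptide
shows at least four *consecutive* b ions or four consecutive y ions,
and the majority of the observed ion intensity is annotated (fragments
within ±20 ppm; reporter peaks count as accounted for). "Majority" is
read literally as strictly more than half, with the threshold
configurable; intensity rather than ion count was chosen as the
"majority" currency because low-intensity noise peaks are abundant and
uninformative. Fragment ladders are b/y at charges 1-2 by default; for
crosslinks the partner peptide plus the crosslink delta is treated as a
fixed mass on the linked residue, appropriate for a non-MS-cleavable
linker backbone.

# Structural interpretation

`checkCrosslink()` measures Cα-Cα distances of crosslinked residue
pairs on a PDB/mmCIF model (first model of multi-model files; altlocs
resolved to the highest-occupancy conformer) through an explicit
protein-to-chain map - no automatic sequence alignment is attempted.
The default maximum of 30 Å follows the accepted restraint for
amine-reactive crosslinkers with spacers near 10-11 Å; it is
configurable because a reagent-specific calibration may be preferred.
`detectSaltBridges()` lists Asp/Glu carboxylate oxygens within 4.0 Å of
a lysine NZ (the documented range for intact bridges is ~2.7-3.8 Å,
broken pairs ≥5 Å). A salt-bridged ε-amine reacts poorly with NHS
esters, so the presence or loss of such a bridge between two states is
the mechanistic reading of a reactivity change at that lysine.

# The synthetic-data generator

`simulateRun()` inverts the quantification model to produce fully
seeded test data: for each site and replicate a true 126-channel
intensity is drawn log-normally (default meanlog `log(5e4)`, sdlog
0.6, a typical reporter intensity scale on Orbitrap-class instruments);
the site's true log2(127/126) ratio plus Gaussian per-spectrum noise
(default SD 0.25, matching the spread seen in well-behaved mixing data)
sets the 127 channel; the pair is forward-mixed through the purity
matrix and emitted as reporter peaks, together with the complete b/y
ladder of a tryptic peptide cut from a bundled *synthetic* toy proteome
(15 invented sequences named after pol II subunits and general
transcription factors so that site keys look realistic), plus uniform
background peaks over 100-1500 m/z that avoid the reporter windows
unless an interference fraction is explicitly requested. Reporter
dropout is modelled as non-detection of one observed reporter peak
(after mixing), the failure mode actually seen in spectra.
`simulateSwap()` produces two such runs with swapped labels and
anti-correlated planted effects.

What the generator emulates: the ratio structure, impurity mixing,
fragment ladders, dropout and reporter-region interference. What it
does not: chromatography and co-elution, isotope envelopes beyond the
2x2 purity model, charge-state diversity of fragments, false
identifications, and intensity-dependent noise. Passing tests therefore
demonstrate that the *computational* pipeline is an exact or unbiased
inverse of the stated forward model - not that the forward model
captures every artifact of real data.

Test and example problem sizes were chosen to keep the suite fast while
leaving sampling error well below the tested tolerances: 50
spectra/site for ratio-recovery checks (standard error 0.035 log2
units), 150 sites for the null-width property, and the interference
worked example uses the full 83,242-spectrum denominator it refers to.

# Known limitations

Only the 2-plex design is implemented end to end (the correction
accepts any invertible n x n matrix, but nothing else is n-plex aware).
Native search-engine support is limited to a pLink2-style CSV and the
package's own interchange TSV; pepXML/mzIdentML are out of scope.
Quantification is MS2 reporter-based only - no MS1 feature matching -
and no significance testing is layered on the fold-change rules, which
mirrors how such experiments are usually interpreted.
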