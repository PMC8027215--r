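---
title: "Models and methods behind sipbands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sipbands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipbands)
```

`sipbands` packages the analysis side of a nucleic-acid stable isotope
probing (SIP) experiment: simulating isopycnic gradient fraction tables,
classifying OTUs as ¹³C-labelled, and predicting labelling levels from
carbon metabolism. This vignette explains the models, the parameters that
matter, and the judgment calls — what a green test establishes and what it
does not.

## The gradient model

A taxon's nucleic acid reaches equilibrium in the gradient at a buoyant
density determined by base composition and isotopic content:

$$\rho = \rho_0(\mathrm{GC}, \text{medium}) + a \cdot \Delta\rho_{\max}(\text{medium})$$

where $a$ is the ¹³C atom fraction of the nucleic-acid carbon.

* **GC → density.** For DNA in CsCl we use the Schildkraut relation
  $\rho_0 = 1.660 + 0.098\cdot\mathrm{GC}$ g/ml, the standard linear map.
  For RNA in CsTFA the default is a constant 1.780 g/ml: rRNA GC spans only
  50–60 mol%, so inter-taxon density differences from base composition are
  negligible relative to labelling shifts. Both the baseline and an
  optional RNA GC slope are arguments of `bd_unlabelled()`.
* **Label → shift.** $\Delta\rho_{\max}$ defaults to 0.036 g/ml (DNA) and
  0.035 g/ml (RNA), the literature full-substitution shifts, linear in the
  atom fraction — the simplest model consistent with higher densities
  marking higher labelling efficiency.
* **Band shape.** Gaussian with $\sigma$ = 0.004 g/ml by default. Real
  band spread depends on fragment length and diffusion and is rarely
  reported; 0.004 g/ml keeps a fully labelled band (~0.035 g/ml away)
  cleanly separated (≈9σ) while spreading each band over 2–3 of the
  default fractions, which is what published fraction profiles look like.
  It is a `gradient_spec()` parameter, not a constant.
* **Fraction grid.** 13 fractions, fraction 1 heaviest, linearly spaced
  1.830→1.750 g/ml (RNA) and 1.740→1.660 g/ml (DNA). Fraction intervals
  for band integration are the midpoints between consecutive densities,
  open-ended at the tails, so band masses sum to one.
* **Sequencing.** Within each fraction the expected composition is each
  taxon's abundance × band mass, renormalized; observed counts are a
  multinomial draw at `read_depth`. Fractions whose total nucleic-acid
  mass falls below `template_floor` (default 10⁻⁴ of community mass) yield
  no data and are recorded as *missing* — emulating fractions where cDNA
  synthesis or PCR fails for lack of template. Missing is never encoded as
  zero: a failed fraction is not evidence of absence.

What the simulator deliberately does **not** model: centrifugation
hydrodynamics and gradient formation, read-level sequences (no FASTQ, no
chimeras, no primer bias), compositional correlation between fractions
beyond shared band physics, and taxon-specific band spread. A green
recovery test therefore establishes that the classifier works when the
gradient physics are as assumed — not that it is robust to, say, smiling
gradients or PCR amplification bias.

## Calibration and the heavy window

The heavy window marks densities where ¹³C-labelled nucleic acid bands.
Two routes:

* **Fixed** (`fixed_calibration()`): 1.797 g/ml (RNA) and 1.702 g/ml
  (DNA), with strong-labelling cutoffs 1.816 and 1.714 g/ml. These are the
  field's standard-derived values for low-GC targets.
* **From standards** (`calibrate()`): given simulated or measured
  single-taxon fully-labelled/unlabelled standard gradients, the threshold
  is the lowest density where the labelled standard's per-fraction mass
  exceeds the unlabelled standard's by 2× and holds at least 1% of the
  labelled total. Calibration needs the per-fraction *mass* profile
  (`total_mass` in the table metadata); a total-sum-scaled single-taxon
  table is uninformative (every column is 1), and the function falls back
  to the fixed defaults with a warning in that case.

One physical caveat the package surfaces rather than hides: calibration on
mid-GC (51%) DNA standards yields a threshold near 1.73 g/ml, well above
the fixed 1.702 g/ml — unlabelled 51%-GC DNA itself bands at ~1.710 g/ml.
An absolute-density threshold from standards is only transferable to
targets of comparable GC; for low-GC targets use the fixed DNA defaults
(or standards of matching GC). For RNA, where base composition hardly
moves the baseline, simulated standards calibrate to within one fraction
width of the fixed 1.797 g/ml value.

The strong cutoff for a standards-derived calibration is the fixed default
for the medium, raised to the threshold if the calibrated threshold
exceeds it.

## The classification procedure

Per OTU, with tables total-sum scaled per fraction:

1. **Background gate.** If the OTU's maximum control-gradient abundance is
   below `background_floor` (default 0.1%), it is *low background*:
   abundance criteria are meaningless (there is nothing to compare
   against), and the **presence rule** applies — labelled if detected
   above the floor in at least one heavy fraction. Such calls get status
   `present_in_heavy`, deliberately distinct from the degree categories:
   presence is detection evidence, not degree evidence.
2. **High-background criteria.** Otherwise the OTU must pass **both**
   the inter-gradient criterion (heavy-window maximum exceeds the maximum
   over *all* control fractions by more than `delta_points`) and the
   intra-gradient criterion (heavy maximum exceeds light maximum by more
   than `delta_points`). `delta_points` defaults to 5 percentage points
   of relative abundance; "more than" is a strict inequality, so an
   exactly-5-point difference does not pass.
3. **Degree.** Passing OTUs are `strongly_labelled` if their peak fraction
   density reaches the strong cutoff, else `partially_labelled`.
4. **GC confound.** If GC contents are supplied, any positive call for a
   taxon whose *unlabelled* band density would already reach the heavy
   threshold is flagged with a warning: its heavy-window presence could be
   GC-driven. For 30 mol% GC DNA (1.6894 g/ml < 1.702 g/ml) the check
   passes and labelling calls stand.

Interpretation choices worth stating: "maximum relative abundance of the
control" is taken over all control fractions (the most conservative
reading); all sub-threshold fractions count as light in criterion 2 (the
window split is exposed via the calibration if an analysis wants
otherwise); the background gate value is a judgment with no published
number behind it, so it is a `thresholds()` parameter; and no
multiple-testing correction is applied — the procedure is threshold-based,
not test-based. Calls are made per gradient; consensus across replicate
gradients is left to the caller, since typical designs pool replicates
before sequencing.

## The recovery world

The package's end-to-end recovery check simulates a ten-taxon community,
all at 30 mol% GC (the GC of the low-GC archaeal genomes that motivate the
DNA defaults) and 10% abundance, with tracked taxa at atom fractions 0,
0.4 and 1.0, sequenced at 50,000 reads per fraction in a CsCl/DNA
gradient, classified against the fixed calibration. The three levels map
cleanly onto the three categories: band centers 1.6894, 1.7038 and
1.7254 g/ml versus thresholds 1.702/1.714 g/ml. The DNA arm is used
deliberately: in an RNA gradient an atom fraction of 0.4 centers at
1.794 g/ml, straddling the 1.797 g/ml threshold — exactly why partially
labelled taxa in RNA-SIP are a borderline observation — and category
recovery there would be a coin toss on band-edge noise, not a test of the
classifier.

`predicted_density_class()` faces the same borderline for RNA. Its default
RNA baseline is 1.784 g/ml — a typical rRNA band position consistent with
the fixed RNA thresholds — under which the mixotrophic prediction (atom
fraction 0.396) lands in the partial class, full labelling in the strong
class, and zero labelling below threshold. The ordering of the three
classes is robust; the exact class of the 0.4 prediction is
calibration-sensitive, and the baseline is an explicit argument.

## Atom tracing

Metabolites are vectors of per-carbon ¹³C probabilities (expectations),
not isotopologue distributions — every reported quantity is a mean atom
fraction, for which expectations compose linearly. Operators conserve
carbon: carboxylation appends one DIC-derived carbon to acetyl-CoA
(unlabelled acetyl + fully labelled CO₂ → pyruvate at 1/3); lactate
oxidation preserves labels position-wise; hexulose condensation joins two
trioses and formaldehyde cleavage removes one designated carbon. Which
hexulose carbon leaves is drawn graphically, not numerically, in pathway
schemes; the only assignment consistent with the 33% → 40% enrichment
step is that the cleaved carbon is organic-derived (unlabelled in the
mixotrophic scenario), so that is the default, with the position index an
argument. The autotrophic scenario assumes every ribose carbon is
DIC-derived (a complete or bypassed H₄MPT Wood–Ljungdahl route); partial
pathway variants are out of scope.

δ¹³C conversions use the VPDB ratio 0.0111802:
$a = R/(1+R)$, $R = R_{\mathrm{VPDB}}(1+\delta/1000)$, exactly invertible
for $\delta > -1000$‰. `mix_toc()` is a two-pool mass balance on atom
fractions, converted back to per mil — the model behind using δ¹³C of
total organic carbon as a community-activity proxy. It assumes the new
biomass adds without remineralizing the old pool.

## Numerical and engineering notes

* Band integrals use `pnorm` differences; the test suite checks them
  against independent `integrate()` quadrature (1,000 randomized cases,
  1e-6 absolute).
* All randomness flows through one integer seed per gradient; derived
  seeds (control, standards) are fixed offsets kept inside 32-bit range.
  Same seed, same inputs → byte-identical outputs.
* Tables are exchanged as TSV plus a sidecar metadata file (density,
  missing flag, total mass per fraction) written at 17 significant
  digits, so round trips are lossless to 1e-12.
* Degenerate inputs: all-zero fractions become missing on scaling;
  pooling a group with a missing member yields a missing pooled fraction;
  an empty heavy window classifies everything unlabelled; identical
  standards trigger the fixed-calibration fallback with a warning.
* Known limitations: no replicate-level statistics, no quantitative
  atom-fraction estimation from observed shifts (the classifier
  categorizes; it does not invert the density model per taxon), and the
  simulator's independence assumptions above.
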