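# Carbon atom tracing through nucleic-acid synthesis.
#
# Metabolites are represented by per-carbon 13C label probabilities
# (expectations), not full isotopologue distributions: every quantity of
# interest here is a mean atom fraction, for which expectations compose
# linearly.

#' Carbon metabolite with per-carbon label probabilities
#'
#' @param name metabolite name.
#' @param carbons numeric vector of per-carbon 13C label probabilities in
#'   \[0, 1\], ordered along the carbon skeleton.
#' @return An object of class `carbon_metabolite`.
#' @export
#' @examples
#' acetyl <- carbon_metabolite("acetyl-CoA", c(0, 0))
#' mean_label(carboxylate(acetyl, dic_label = 1))  # 1/3
carbon_metabolite <- function(name, carbons) {
  if (length(carbons) == 0L) stop("metabolite needs at least one carbon", call. = FALSE)
  check_fraction(carbons, "carbons")
  structure(list(name = name, carbons = as.numeric(carbons)),
            class = "carbon_metabolite")
}

#' @export
print.carbon_metabolite <- function(x, ...) {
  cat(sprintf("<%s> %d C: [%s], mean label %.4f\n", x$name, length(x$carbons),
              paste(signif(x$carbons, 4), collapse = ", "), mean_label(x)))
  invisible(x)
}

#' @rdname carbon_metabolite
#' @param x a `carbon_metabolite`.
#' @export
mean_label <- function(x) mean(x$carbons)

#' @rdname carbon_metabolite
#' @export
n_carbons <- function(x) length(x$carbons)

check_carbons <- function(x, n, what) {
  if (!inherits(x, "carbon_metabolite") || n_carbons(x) != n) {
    stop(sprintf("%s must be a carbon_metabolite with %d carbons", what, n),
         call. = FALSE)
  }
  invisible(x)
}

#' Carboxylation of acetyl-CoA to pyruvate
#'
#' Pyruvate synthesis from acetyl-CoA incorporates one CO2: the two acetyl
#' carbons are retained and a third carbon drawn from the dissolved
#' inorganic carbon (DIC) pool is appended (carboxyl position). With
#' unlabelled acetyl-CoA and a fully 13C-labelled DIC pool the mean
#' pyruvate label is therefore 1/3 (33%).
#'
#' @param acetyl a 2-carbon [carbon_metabolite()].
#' @param dic_label 13C fraction of the DIC pool, in \[0, 1\].
#' @return A 3-carbon pyruvate `carbon_metabolite`; carbons 1-2 from
#'   acetyl, carbon 3 from DIC.
#' @export
carboxylate <- function(acetyl, dic_label) {
  check_carbons(acetyl, 2L, "acetyl")
  check_fraction(dic_label, "dic_label")
  carbon_metabolite("pyruvate", c(acetyl$carbons, dic_label))
}

#' Lactate oxidation to pyruvate
#'
#' Lactate dehydrogenases and lactate utilization proteins oxidize lactate
#' to pyruvate without making or breaking carbon-carbon bonds, so the three
#' carbon labels carry over position-wise and no inorganic carbon is
#' incorporated.
#'
#' @param lactate a 3-carbon [carbon_metabolite()].
#' @return A 3-carbon pyruvate with identical carbon labels.
#' @export
lactate_to_pyruvate <- function(lactate) {
  check_carbons(lactate, 3L, "lactate")
  carbon_metabolite("pyruvate", lactate$carbons)
}

#' Ribose formation via hexulose condensation and formaldehyde cleavage
#'
#' Two pyruvate-derived triose units condense to a six-carbon
#' arabino-3-hexulose-6-phosphate; cleavage of one carbon as formaldehyde
#' leaves the five ribose carbons. Which hexulose carbon leaves is set by
#' `formaldehyde_position` (an index into the concatenated
#' `c(triose1, triose2)` skeleton). The default, position 1, is an
#' organic-derived carbon: in the mixotrophic scenario (unlabelled organic
#' carbon + labelled DIC) the cleaved carbon is unlabelled, which is the
#' assignment that raises the mean label from 1/3 in pyruvate to 2/5 (40%)
#' in ribose.
#'
#' @param triose1,triose2 3-carbon [carbon_metabolite()]s.
#' @param formaldehyde_position index (1-6) of the hexulose carbon cleaved
#'   as formaldehyde.
#' @return A 5-carbon ribose `carbon_metabolite`.
#' @export
ribose_from_pyruvate <- function(triose1, triose2, formaldehyde_position = 1L) {
  check_carbons(triose1, 3L, "triose1")
  check_carbons(triose2, 3L, "triose2")
  if (!formaldehyde_position %in% 1:6) {
    stop("`formaldehyde_position` must be an index between 1 and 6", call. = FALSE)
  }
  hexulose <- c(triose1$carbons, triose2$carbons)
  carbon_metabolite("ribose", hexulose[-formaldehyde_position])
}

#' Labelling scenario
#'
#' The substrate context of an incubation: which organic carbon source
#' feeds nucleic-acid synthesis and how labelled the DIC pool is.
#'
#' * `"unlabelled_polymer"` — mixotrophy: acetyl-CoA from unlabelled
#'   organic carbon (long-chain fatty acids, aromatic polymers, methyl
#'   substrates), carboxylated with DIC-derived CO2.
#' * `"labelled_lactate"` — heterotrophy on labelled lactate: pyruvate from
#'   lactate is used directly, without inorganic carbon incorporation.
#' * `"none_autotrophic"` — autotrophy: all carbon from the DIC pool via
#'   the (H4MPT-dependent Wood-Ljungdahl) CO2-fixation route.
#'
#' @param organic_substrate one of `"unlabelled_polymer"`,
#'   `"labelled_lactate"`, `"none_autotrophic"`.
#' @param dic_label 13C atom fraction of the DIC pool, in \[0, 1\].
#' @param substrate_label 13C atom fraction of a labelled organic substrate
#'   (per carbon); default 0.99, matching 99% 13C-labelled amendments.
#' @return An object of class `sip_scenario`.
#' @export
scenario <- function(organic_substrate = c("unlabelled_polymer",
                                           "labelled_lactate",
                                           "none_autotrophic"),
                     dic_label = 0,
                     substrate_label = 0.99) {
  organic_substrate <- match.arg(organic_substrate)
  check_fraction(dic_label, "dic_label")
  check_fraction(substrate_label, "substrate_label")
  structure(list(organic_substrate = organic_substrate,
                 dic_label = dic_label,
                 substrate_label = substrate_label),
            class = "sip_scenario")
}

#' Predict the ribose 13C atom fraction under a scenario
#'
#' Composes the atom-tracing operators for the given scenario and returns
#' the mean 13C atom fraction of nucleic-acid ribose. Mixotrophy on
#' unlabelled polymers with DIC label d gives 2d/5 (0.396 at d = 0.99);
#' heterotrophy on labelled lactate conserves the substrate label (0.99);
#' autotrophy gives d for all carbons.
#'
#' @param sc a [scenario()].
#' @return Atom fraction in \[0, 1\].
#' @export
#' @examples
#' predict_ribose_label(scenario("unlabelled_polymer", dic_label = 1)) # 0.40
predict_ribose_label <- function(sc) {
  stopifnot(inherits(sc, "sip_scenario"))
  pyr <- switch(sc$organic_substrate,
    unlabelled_polymer = carboxylate(
      carbon_metabolite("acetyl-CoA", c(0, 0)), sc$dic_label),
    labelled_lactate = lactate_to_pyruvate(
      carbon_metabolite("lactate", rep(sc$substrate_label, 3))),
    none_autotrophic = carboxylate(
      carbon_metabolite("acetyl-CoA", rep(sc$dic_label, 2)), sc$dic_label)
  )
  # Both trioses entering the hexulose derive from the same pyruvate pool;
  # pyruvate carbons 1-2 are acetyl-derived, carbon 3 carboxyl-derived. The
  # cleaved formaldehyde carbon is an acetyl-derived (position 1) carbon.
  triose <- carbon_metabolite("triose", pyr$carbons)
  mean_label(ribose_from_pyruvate(triose, triose, formaldehyde_position = 1L))
}

#' Expected density class for a labelling level
#'
#' Places the expected band center of nucleic acid at the given 13C atom
#' fraction (baseline density + labelling shift) against a calibration's
#' heavy and strong cutoffs. The default baseline is 1.784 g/ml for RNA — a
#' typical rRNA band position for the 50-60 mol% GC of rRNA, and
#' deliberately calibration-consistent with the fixed RNA thresholds — and
#' the mid-GC DNA density `bd_unlabelled(0.5, "dna")` for DNA.
#'
#' @param atom_fraction 13C atom fraction of the nucleic acid.
#' @inheritParams bd_unlabelled
#' @param cal a `sip_calibration`.
#' @param baseline unlabelled band density in g/ml; `NULL` for the medium
#'   default described above.
#' @return Ordered factor with levels `unlabelled < partial < strong`.
#' @export
predicted_density_class <- function(atom_fraction, medium, cal = fixed_calibration(medium),
                                    baseline = NULL) {
  check_fraction(atom_fraction, "atom_fraction")
  medium <- match_medium(medium)
  stopifnot(inherits(cal, "sip_calibration"))
  if (is.null(baseline)) {
    baseline <- if (medium == "CsTFA_RNA") 1.784 else bd_unlabelled(0.5, medium)
  }
  center <- baseline + density_shift(atom_fraction, medium)
  cls <- ifelse(center >= cal$strong_density, "strong",
                ifelse(center >= cal$threshold_density, "partial", "unlabelled"))
  factor(cls, levels = c("unlabelled", "partial", "strong"), ordered = TRUE)
}

#' delta-13C / atom-fraction conversions and TOC mixing
#'
#' Standard VPDB conversions between the per-mil delta-13C scale and the
#' 13C atom fraction, with `R_VPDB = 0.0111802`:
#' \eqn{R = R_{VPDB}(1 + \delta/1000)}, atom fraction \eqn{= R/(1+R)}.
#' `mix_toc()` is the two-pool isotope mass balance behind delta-13C of
#' total organic carbon (TOC) as an assimilation proxy: a fraction `f_new`
#' of the TOC pool is replaced by new biomass at atom fraction `af_new` and
#' the mixed pool is converted back to per mil.
#'
#' @param delta13c delta-13C in per mil vs VPDB; must be > -1000.
#' @return `delta_to_atom_fraction()` an atom fraction in (0, 1);
#'   `atom_fraction_to_delta()` per mil; the two are exact inverses.
#' @export
#' @examples
#' delta_to_atom_fraction(0)          # 0.011056...
#' atom_fraction_to_delta(0.5)        # ~88,444 per mil
#' mix_toc(-20, f_new = 0.01, af_new = 0.40)
delta_to_atom_fraction <- function(delta13c) {
  check_scalar_number(delta13c, "delta13c")
  if (delta13c <= -1000) stop("`delta13c` must be > -1000 per mil", call. = FALSE)
  r <- R_VPDB * (1 + delta13c / 1000)
  r / (1 + r)
}

R_VPDB <- 0.0111802

#' @rdname delta_to_atom_fraction
#' @param atom_fraction 13C atom fraction in \[0, 1).
#' @export
atom_fraction_to_delta <- function(atom_fraction) {
  check_fraction(atom_fraction, "atom_fraction")
  if (atom_fraction >= 1) stop("`atom_fraction` must be < 1", call. = FALSE)
  r <- atom_fraction / (1 - atom_fraction)
  (r / R_VPDB - 1) * 1000
}

#' @rdname delta_to_atom_fraction
#' @param delta_old delta-13C of the existing TOC pool, per mil.
#' @param f_new fraction of the pool replaced by new biomass, in \[0, 1\].
#' @param af_new 13C atom fraction of the new biomass.
#' @export
mix_toc <- function(delta_old, f_new, af_new) {
  check_fraction(f_new, "f_new")
  check_fraction(af_new, "af_new")
  af <- (1 - f_new) * delta_to_atom_fraction(delta_old) + f_new * af_new
  atom_fraction_to_delta(af)
}
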