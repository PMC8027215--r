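#' Gradient media
#'
#' Nucleic-acid SIP uses two gradient media: CsCl for DNA and CsTFA for RNA.
#' Functions in this package accept either the full medium name
#' (`"CsCl_DNA"`, `"CsTFA_RNA"`) or the shorthand `"dna"` / `"rna"`.
#'
#' @param medium character; medium name or shorthand.
#' @return The canonical medium string.
#' @export
#' @examples
#' match_medium("rna")
match_medium <- function(medium) {
  if (!is.character(medium) || length(medium) != 1L) {
    stop("`medium` must be a single string", call. = FALSE)
  }
  key <- tolower(medium)
  out <- switch(key,
    "cscl_dna" = "CsCl_DNA", "dna" = "CsCl_DNA",
    "cstfa_rna" = "CsTFA_RNA", "rna" = "CsTFA_RNA",
    NULL
  )
  if (is.null(out)) {
    stop(sprintf("unknown medium '%s'; use 'CsCl_DNA'/'dna' or 'CsTFA_RNA'/'rna'",
                 medium), call. = FALSE)
  }
  out
}

#' Buoyant density of unlabelled nucleic acid
#'
#' Maps GC content to the equilibrium buoyant density of unlabelled nucleic
#' acid. For DNA in CsCl the Schildkraut linear relation is used,
#' \eqn{\rho = 1.660 + 0.098 \cdot GC} g/ml. For RNA in CsTFA the density is
#' taken as a constant baseline (default 1.780 g/ml) with an optional weak GC
#' slope: rRNA spans only a narrow GC range (50--60 mol%), so GC-driven
#' density differences between taxa are negligible there.
#'
#' @param gc GC content as a fraction in \[0, 1\] (G+C mol% / 100).
#' @param medium gradient medium, see [match_medium()].
#' @param rna_baseline baseline CsTFA density for RNA, g/ml.
#' @param rna_gc_slope optional GC dependence for RNA, g/ml per GC unit.
#' @return Buoyant density in g/ml.
#' @export
#' @examples
#' bd_unlabelled(0.30, "dna") # 1.6894 g/ml, a low-GC archaeal genome
#' bd_unlabelled(0.55, "rna") # constant RNA baseline
bd_unlabelled <- function(gc, medium, rna_baseline = 1.780, rna_gc_slope = 0) {
  check_fraction(gc, "gc")
  medium <- match_medium(medium)
  if (medium == "CsCl_DNA") {
    1.660 + 0.098 * gc
  } else {
    rna_baseline + rna_gc_slope * gc
  }
}

#' Density shift from 13C labelling
#'
#' Full 13C substitution increases the buoyant density of nucleic acid by a
#' medium-dependent maximum shift; intermediate atom fractions shift
#' proportionally. Defaults are 0.036 g/ml (DNA, CsCl) and 0.035 g/ml
#' (RNA, CsTFA), the literature full-label shifts.
#'
#' @param atom_fraction_13c 13C atom fraction of the nucleic-acid carbon, in
#'   \[0, 1\].
#' @inheritParams bd_unlabelled
#' @param max_shift override of the full-label shift in g/ml; `NULL` uses the
#'   medium default.
#' @return Density increase in g/ml, monotone in `atom_fraction_13c`.
#' @export
#' @examples
#' density_shift(1.0, "dna")  # 0.036 g/ml
#' density_shift(0.4, "rna")  # 0.014 g/ml
density_shift <- function(atom_fraction_13c, medium, max_shift = NULL) {
  check_fraction(atom_fraction_13c, "atom_fraction_13c")
  medium <- match_medium(medium)
  if (is.null(max_shift)) {
    max_shift <- if (medium == "CsCl_DNA") 0.036 else 0.035
  }
  atom_fraction_13c * max_shift
}

#' Default fraction density grids
#'
#' Thirteen fractions per gradient, fraction 1 heaviest (bottom of the
#' gradient), linearly spaced: 1.830 to 1.750 g/ml for RNA (CsTFA) and 1.740
#' to 1.660 g/ml for DNA (CsCl).
#'
#' @inheritParams bd_unlabelled
#' @return Numeric vector of 13 strictly decreasing densities (g/ml).
#' @export
default_fraction_densities <- function(medium) {
  medium <- match_medium(medium)
  if (medium == "CsCl_DNA") {
    seq(1.740, 1.660, length.out = 13L)
  } else {
    seq(1.830, 1.750, length.out = 13L)
  }
}

#' Specify a synthetic gradient
#'
#' Bundles the physical and sampling parameters of one simulated isopycnic
#' gradient: the medium, the 13-fraction density grid, the within-taxon band
#' spread, the per-fraction sequencing depth, the template floor below which
#' a fraction yields no sequence data (emulating failed cDNA synthesis or PCR
#' from near-empty fractions), and the random seed.
#'
#' @inheritParams bd_unlabelled
#' @param fraction_densities strictly decreasing densities in g/ml, fraction
#'   1 heaviest; must have 13 elements.
#' @param band_sigma Gaussian band spread (standard deviation), g/ml.
#' @param read_depth sequencing reads per non-missing fraction.
#' @param template_floor fraction of total community nucleic-acid mass below
#'   which a gradient fraction is recorded as missing.
#' @param seed integer seed governing all sampling for this gradient.
#' @return An object of class `gradient_spec`.
#' @export
#' @examples
#' gradient_spec("dna", read_depth = 1000, seed = 42)
gradient_spec <- function(medium,
                          fraction_densities = default_fraction_densities(medium),
                          band_sigma = 0.004,
                          read_depth = 50000L,
                          template_floor = 1e-4,
                          seed = 1L) {
  medium <- match_medium(medium)
  if (length(fraction_densities) != 13L) {
    stop("`fraction_densities` must contain exactly 13 densities", call. = FALSE)
  }
  if (any(diff(fraction_densities) >= 0)) {
    stop("`fraction_densities` must be strictly decreasing (fraction 1 heaviest)",
         call. = FALSE)
  }
  check_scalar_number(band_sigma, "band_sigma")
  if (band_sigma <= 0) stop("`band_sigma` must be > 0", call. = FALSE)
  check_scalar_number(read_depth, "read_depth")
  if (read_depth < 1) stop("`read_depth` must be >= 1", call. = FALSE)
  check_scalar_number(template_floor, "template_floor")
  structure(
    list(medium = medium,
         fraction_densities = as.numeric(fraction_densities),
         band_sigma = band_sigma,
         read_depth = as.integer(read_depth),
         template_floor = template_floor,
         seed = as.integer(seed)),
    class = "gradient_spec"
  )
}

#' @export
print.gradient_spec <- function(x, ...) {
  cat(sprintf("<gradient_spec> %s, 13 fractions %.4f..%.4f g/ml, sigma %.4f, depth %d, seed %d\n",
              x$medium, max(x$fraction_densities), min(x$fraction_densities),
              x$band_sigma, x$read_depth, x$seed))
  invisible(x)
}

#' Define a community of taxa
#'
#' A community is a data frame with one row per taxon: `taxon_id`, `gc`
#' (G+C mol% / 100), `abundance` (community proportion, summing to 1) and
#' `atom_fraction_13c` (13C atom fraction of the taxon's nucleic acid).
#'
#' @param taxon_id character vector of unique taxon identifiers.
#' @param gc,abundance,atom_fraction_13c numeric vectors in \[0, 1\],
#'   recycled to the length of `taxon_id`.
#' @return A tibble with class column types validated; abundances must sum
#'   to 1 within 1e-9.
#' @export
#' @examples
#' community(c("A", "B"), gc = 0.3, abundance = c(0.7, 0.3),
#'           atom_fraction_13c = c(0, 1))
community <- function(taxon_id, gc, abundance, atom_fraction_13c) {
  if (length(taxon_id) == 0L) stop("community must contain at least one taxon", call. = FALSE)
  if (anyDuplicated(taxon_id)) {
    stop(sprintf("duplicate taxon_id: %s",
                 paste(unique(taxon_id[duplicated(taxon_id)]), collapse = ", ")),
         call. = FALSE)
  }
  n <- length(taxon_id)
  out <- tibble::tibble(
    taxon_id = as.character(taxon_id),
    gc = rep_len(gc, n),
    abundance = rep_len(abundance, n),
    atom_fraction_13c = rep_len(atom_fraction_13c, n)
  )
  check_fraction(out$gc, "gc")
  check_fraction(out$abundance, "abundance")
  check_fraction(out$atom_fraction_13c, "atom_fraction_13c")
  if (abs(sum(out$abundance) - 1) > 1e-9) {
    stop(sprintf("community abundances must sum to 1 (got %.12f)", sum(out$abundance)),
         call. = FALSE)
  }
  out
}

# Density interval boundaries of each fraction: midpoints between consecutive
# grid densities, open-ended at both tails. Returns list(lower, upper).
fraction_bounds <- function(densities) {
  mids <- (densities[-1] + densities[-length(densities)]) / 2
  list(lower = c(mids, -Inf), upper = c(Inf, mids))
}

#' Equilibrium band center of a taxon
#'
#' @param gc GC fraction of the taxon.
#' @param atom_fraction_13c 13C atom fraction of its nucleic acid.
#' @inheritParams bd_unlabelled
#' @param ... passed to [bd_unlabelled()] and [density_shift()].
#' @return Band center density in g/ml.
#' @export
band_center <- function(gc, atom_fraction_13c, medium, ...) {
  args <- list(...)
  bd_args <- args[names(args) %in% c("rna_baseline", "rna_gc_slope")]
  sh_args <- args[names(args) %in% "max_shift"]
  do.call(bd_unlabelled, c(list(gc = gc, medium = medium), bd_args)) +
    do.call(density_shift, c(list(atom_fraction_13c = atom_fraction_13c,
                                  medium = medium), sh_args))
}

#' Discretized equilibrium band of a taxon
#'
#' Integrates the taxon's Gaussian equilibrium band (centered at
#' `bd_unlabelled(gc) + density_shift(atom_fraction)`, sd = `band_sigma`)
#' over each fraction's density interval. Intervals are the midpoints between
#' consecutive fraction densities, open-ended at both tails, so the masses
#' sum to 1.
#'
#' @param taxon a one-row data frame or list with fields `gc` and
#'   `atom_fraction_13c` (e.g. one row of [community()]).
#' @param spec a [gradient_spec()].
#' @return Numeric vector of per-fraction band masses, named by fraction id.
#' @export
#' @examples
#' sp <- gradient_spec("dna")
#' band_profile(list(gc = 0.30, atom_fraction_13c = 0), sp)
band_profile <- function(taxon, spec) {
  stopifnot(inherits(spec, "gradient_spec"))
  center <- band_center(taxon$gc, taxon$atom_fraction_13c, spec$medium)
  b <- fraction_bounds(spec$fraction_densities)
  mass <- stats::pnorm(b$upper, mean = center, sd = spec$band_sigma) -
    stats::pnorm(b$lower, mean = center, sd = spec$band_sigma)
  names(mass) <- default_fraction_ids(length(mass))
  mass
}

default_fraction_ids <- function(n) sprintf("F%02d", seq_len(n))

#' Simulate sequencing of one gradient
#'
#' Computes each taxon's expected nucleic-acid mass per fraction
#' (abundance x band mass), marks fractions whose total mass falls below the
#' template floor as missing, draws multinomial read counts at the specified
#' depth for the remaining fractions, and total-sum scales the result. The
#' returned [fraction_table()] retains the raw counts and the per-fraction
#' total mass, which downstream pooling and calibration use.
#'
#' @param community a [community()] data frame.
#' @param spec a [gradient_spec()].
#' @return A total-sum-scaled `fraction_table` with `counts` and per-fraction
#'   `total_mass` retained.
#' @export
#' @examples
#' com <- community(c("A", "B"), gc = 0.3, abundance = c(0.5, 0.5),
#'                  atom_fraction_13c = c(0, 1))
#' simulate_gradient(com, gradient_spec("dna", read_depth = 1000, seed = 7))
simulate_gradient <- function(community, spec) {
  stopifnot(inherits(spec, "gradient_spec"))
  if (is.null(community) || nrow(community) == 0L) {
    stop("community is empty", call. = FALSE)
  }
  if (abs(sum(community$abundance) - 1) > 1e-9) {
    stop("community abundances must sum to 1", call. = FALSE)
  }
  n_frac <- length(spec$fraction_densities)
  mass <- t(vapply(seq_len(nrow(community)), function(i) {
    community$abundance[i] * band_profile(community[i, ], spec)
  }, numeric(n_frac)))
  rownames(mass) <- community$taxon_id
  total <- colSums(mass)
  missing <- total < spec$template_floor
  counts <- matrix(NA_real_, nrow(mass), ncol(mass),
                   dimnames = dimnames(mass))
  withr::with_seed(spec$seed, {
    for (j in which(!missing)) {
      counts[, j] <- stats::rmultinom(1L, size = spec$read_depth,
                                      prob = mass[, j])[, 1L]
    }
  })
  ft <- fraction_table(values = counts,
                       densities = spec$fraction_densities,
                       fraction_ids = default_fraction_ids(n_frac),
                       missing = missing,
                       total_mass = total,
                       normalized = FALSE)
  total_sum_scale(ft)
}

#' Simulate standard gradients
#'
#' Generates the pair of single-taxon standard gradients used for density
#' calibration: an unlabelled standard and a highly labelled one (default
#' 99% 13C), mimicking fully labelled and unlabelled E. coli nucleic-acid
#' standards run alongside sample gradients.
#'
#' @param spec a [gradient_spec()]; the labelled standard uses `seed + 1`.
#' @param gc_standard GC fraction of the standard organism (E. coli ~0.51).
#' @param label_high 13C atom fraction of the labelled standard, in (0, 1\].
#' @return A list with elements `unlabelled` and `labelled`, each a
#'   `fraction_table`.
#' @export
simulate_standards <- function(spec, gc_standard = 0.51, label_high = 0.99) {
  stopifnot(inherits(spec, "gradient_spec"))
  check_fraction(gc_standard, "gc_standard")
  check_fraction(label_high, "label_high")
  unl <- community("standard", gc = gc_standard, abundance = 1,
                   atom_fraction_13c = 0)
  lab <- community("standard", gc = gc_standard, abundance = 1,
                   atom_fraction_13c = label_high)
  spec_lab <- spec
  spec_lab$seed <- offset_seed(spec$seed, 1)
  list(unlabelled = simulate_gradient(unl, spec),
       labelled = simulate_gradient(lab, spec_lab))
}
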