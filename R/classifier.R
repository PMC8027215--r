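#' Classification thresholds
#'
#' The two tunables of the labelling criteria: `delta_points`, the
#' percentage-point increase in relative abundance that criteria 1 and 2
#' must exceed ("more than 5%" — strictly greater than, so an exactly
#' 5-point difference does not pass), and `background_floor`, the relative
#' abundance below which an OTU counts as not detectable in control
#' gradients and is routed to the presence rule instead.
#'
#' @param delta_points percentage points (default 5).
#' @param background_floor relative abundance (default 0.001 = 0.1%).
#' @return An object of class `sip_thresholds`.
#' @export
thresholds <- function(delta_points = 5, background_floor = 0.001) {
  check_scalar_number(delta_points, "delta_points")
  if (delta_points <= 0) stop("`delta_points` must be > 0", call. = FALSE)
  check_scalar_number(background_floor, "background_floor")
  structure(list(delta_points = delta_points,
                 background_floor = background_floor),
            class = "sip_thresholds")
}

new_calibration <- function(medium, threshold_density, strong_density, source) {
  if (strong_density < threshold_density) {
    stop("strong_density must be >= threshold_density", call. = FALSE)
  }
  structure(list(medium = medium,
                 threshold_density = threshold_density,
                 strong_density = strong_density,
                 source = source),
            class = "sip_calibration")
}

#' @export
print.sip_calibration <- function(x, ...) {
  cat(sprintf("<sip_calibration> %s: heavy >= %.4f g/ml, strong >= %.4f g/ml (%s)\n",
              x$medium, x$threshold_density, x$strong_density, x$source))
  invisible(x)
}

#' Fixed heavy-window calibration
#'
#' The standard-gradient-derived density thresholds marking 13C-labelled
#' nucleic acids: 1.797 g/ml for RNA (CsTFA) and 1.702 g/ml for DNA (CsCl),
#' with strong-labelling cutoffs of 1.816 g/ml (RNA) and 1.714 g/ml (DNA).
#'
#' @inheritParams bd_unlabelled
#' @return A calibration object with `source = "fixed"`.
#' @export
fixed_calibration <- function(medium) {
  medium <- match_medium(medium)
  if (medium == "CsTFA_RNA") {
    new_calibration(medium, 1.797, 1.816, "fixed")
  } else {
    new_calibration(medium, 1.702, 1.714, "fixed")
  }
}

default_strong_density <- function(medium) {
  if (match_medium(medium) == "CsTFA_RNA") 1.816 else 1.714
}

#' Calibrate the heavy window from standard gradients
#'
#' Derives the heavy-window density threshold from a pair of single-taxon
#' standard gradients (fully labelled vs unlabelled). The threshold is the
#' lowest density at which the labelled standard's per-fraction mass both
#' exceeds the unlabelled standard's by `factor` (default 2x) and exceeds
#' `mass_floor` (default 1%) of the labelled standard's total mass. When the
#' standards carry no per-fraction mass information or no fraction
#' separates them (e.g. an unlabelled "labelled" standard), the fixed
#' defaults for the medium are returned with a warning.
#'
#' The strong-labelling cutoff is the fixed default for the medium, raised
#' to the threshold if the calibrated threshold exceeds it.
#'
#' @param unlabelled,labelled single-OTU [fraction_table()]s on the same
#'   fraction grid, e.g. from [simulate_standards()].
#' @inheritParams bd_unlabelled
#' @param factor required mass excess of labelled over unlabelled.
#' @param mass_floor required mass as a fraction of the labelled standard's
#'   total.
#' @return An object of class `sip_calibration`.
#' @export
calibrate <- function(unlabelled, labelled, medium, factor = 2, mass_floor = 0.01) {
  stopifnot(inherits(unlabelled, "fraction_table"),
            inherits(labelled, "fraction_table"))
  medium <- match_medium(medium)
  if (nrow(unlabelled$values) != 1L || nrow(labelled$values) != 1L) {
    stop("standard gradients must contain a single taxon", call. = FALSE)
  }
  if (!isTRUE(all.equal(unlabelled$fractions$density, labelled$fractions$density))) {
    stop("standard gradients must share the same fraction density grid", call. = FALSE)
  }
  m_unl <- unlabelled$fractions$total_mass
  m_lab <- labelled$fractions$total_mass
  if (all(is.na(m_unl)) || all(is.na(m_lab))) {
    warning("standards carry no per-fraction mass; falling back to fixed calibration")
    return(fixed_calibration(medium))
  }
  m_unl[is.na(m_unl)] <- 0
  m_lab[is.na(m_lab)] <- 0
  p_unl <- m_unl / sum(m_unl)
  p_lab <- m_lab / sum(m_lab)
  ok <- p_lab > factor * p_unl & p_lab > mass_floor
  if (!any(ok)) {
    warning("standards do not separate; falling back to fixed calibration")
    return(fixed_calibration(medium))
  }
  thr <- min(labelled$fractions$density[ok])
  new_calibration(medium, thr, max(thr, default_strong_density(medium)),
                  "standards")
}

#' Assign fractions to density windows
#'
#' Splits a gradient's fractions into the heavy window (density at or above
#' the calibrated threshold, marking 13C-labelled nucleic acid) and the
#' light window below it. For reporting parity with pooled RNA-SIP layouts,
#' fractions are additionally ranked into four bands
#' (heavy/middle/light/ultra_light) by density.
#'
#' @param x a [fraction_table()].
#' @param cal a calibration from [calibrate()] or [fixed_calibration()].
#' @return A data frame: `fraction_id`, `density`, `missing`, `window`
#'   ("heavy"/"light"), `band`.
#' @export
partition_windows <- function(x, cal) {
  stopifnot(inherits(x, "fraction_table"), inherits(cal, "sip_calibration"))
  dens <- x$fractions$density
  band_levels <- c("heavy", "middle", "light", "ultra_light")
  rank4 <- ceiling(rank(-dens, ties.method = "first") / length(dens) * 4)
  data.frame(
    fraction_id = x$fractions$fraction_id,
    density = dens,
    missing = x$fractions$missing,
    window = ifelse(dens >= cal$threshold_density, "heavy", "light"),
    band = band_levels[rank4],
    stringsAsFactors = FALSE
  )
}

# Maximum abundance of `otu` over the given fraction ids, ignoring missing
# fractions; 0 when no usable fraction remains.
max_abund <- function(x, otu, frac_ids) {
  v <- otu_abundance(x, otu)
  keep <- x$fractions$fraction_id %in% frac_ids & !x$fractions$missing
  if (!any(keep)) return(0)
  max(v[keep], na.rm = TRUE)
}

#' Criterion 1: inter-gradient comparison
#'
#' Passes when the OTU's maximum relative abundance in the heavy fractions
#' of the labelled (substrate-amended) gradient exceeds its maximum relative
#' abundance over all fractions of the control gradient by more than
#' `delta_points` percentage points.
#'
#' @param otu OTU id.
#' @param labelled,control total-sum-scaled [fraction_table()]s.
#' @param windows window assignment from [partition_windows()] for the
#'   labelled gradient.
#' @param thr a [thresholds()] object.
#' @return A list with `pass` (logical) and `evidence` (named percentages).
#' @export
criterion_inter <- function(otu, labelled, control, windows, thr = thresholds()) {
  heavy_ids <- windows$fraction_id[windows$window == "heavy"]
  heavy_max <- max_abund(labelled, otu, heavy_ids)
  control_max <- max_abund(control, otu, control$fractions$fraction_id)
  diff_pts <- (heavy_max - control_max) * 100
  list(pass = diff_pts > thr$delta_points,
       evidence = c(heavy_max_pct = heavy_max * 100,
                    control_max_pct = control_max * 100,
                    inter_diff_pts = diff_pts))
}

#' Criterion 2: intra-gradient evaluation
#'
#' Passes when the OTU's maximum relative abundance in the heavy window of
#' the labelled gradient exceeds its maximum in the light window by more
#' than `delta_points` percentage points.
#'
#' @inheritParams criterion_inter
#' @return A list with `pass` and `evidence`.
#' @export
criterion_intra <- function(otu, labelled, windows, thr = thresholds()) {
  heavy_ids <- windows$fraction_id[windows$window == "heavy"]
  light_ids <- windows$fraction_id[windows$window == "light"]
  heavy_max <- max_abund(labelled, otu, heavy_ids)
  light_max <- max_abund(labelled, otu, light_ids)
  diff_pts <- (heavy_max - light_max) * 100
  list(pass = diff_pts > thr$delta_points,
       evidence = c(heavy_max_pct = heavy_max * 100,
                    light_max_pct = light_max * 100,
                    intra_diff_pts = diff_pts))
}

#' Presence rule for low-background OTUs
#'
#' The relative-abundance criteria cannot be applied to OTUs that are not
#' detectable in control gradients. For such OTUs (maximum control abundance
#' below `background_floor`), label incorporation is instead called from
#' their presence (abundance above the floor) in at least one heavy fraction
#' of the labelled gradient.
#'
#' @inheritParams criterion_inter
#' @return A list with `applicable`, `pass`, and `evidence`.
#' @export
presence_rule <- function(otu, labelled, control, windows, thr = thresholds()) {
  control_max <- max_abund(control, otu, control$fractions$fraction_id)
  applicable <- control_max < thr$background_floor
  heavy_ids <- windows$fraction_id[windows$window == "heavy"]
  v <- otu_abundance(labelled, otu)
  keep <- labelled$fractions$fraction_id %in% heavy_ids & !labelled$fractions$missing
  detected <- any(v[keep] > thr$background_floor, na.rm = TRUE)
  list(applicable = applicable,
       pass = applicable && detected,
       evidence = c(control_max_pct = control_max * 100,
                    heavy_max_pct = max_abund(labelled, otu, heavy_ids) * 100))
}

#' GC-confound check
#'
#' Unlabelled high-GC DNA bands at high density and could mimic labelling.
#' The check passes (returns `TRUE`, no confound) when the unlabelled
#' buoyant density implied by the taxon's GC content lies below the heavy
#' threshold, so heavy-fraction presence cannot be GC-driven. A `FALSE`
#' means heavy-window calls for this taxon must be treated as warnings.
#'
#' @param gc GC fraction of the taxon's nucleic acid.
#' @inheritParams bd_unlabelled
#' @param cal a `sip_calibration`.
#' @return Logical: `TRUE` if no GC confound is possible.
#' @export
#' @examples
#' gc_confound_check(0.30, "dna", fixed_calibration("dna")) # TRUE: 1.6894 < 1.702
gc_confound_check <- function(gc, medium, cal) {
  stopifnot(inherits(cal, "sip_calibration"))
  bd_unlabelled(gc, medium) < cal$threshold_density
}

#' Classify OTUs as 13C-labelled or not
#'
#' Applies the full decision procedure per OTU. OTUs with a high control
#' background (maximum control abundance at or above `background_floor`)
#' must pass both the inter-gradient criterion ([criterion_inter()]) and
#' the intra-gradient criterion ([criterion_intra()]); passing OTUs are
#' `strongly_labelled` when their labelled-gradient peak fraction density
#' reaches the strong cutoff and `partially_labelled` otherwise. OTUs not
#' detectable in controls are routed to the [presence_rule()] and called
#' `present_in_heavy` when it passes. Everything else is `unlabelled`.
#' When taxon GC contents are supplied, [gc_confound_check()] is run and
#' failing positive calls are flagged with a warning.
#'
#' @param labelled,control total-sum-scaled [fraction_table()]s over the
#'   same OTUs.
#' @param cal a `sip_calibration`.
#' @param thr a [thresholds()] object.
#' @param gc optional named numeric vector of GC fractions per OTU.
#' @return A tibble, one row per OTU: `otu_id`, `status`, `background`,
#'   `criterion1`, `criterion2`, `presence`, `peak_density`, evidence
#'   percentages, and `gc_confound_ok`.
#' @export
classify_otus <- function(labelled, control, cal, thr = thresholds(), gc = NULL) {
  stopifnot(inherits(labelled, "fraction_table"),
            inherits(control, "fraction_table"),
            inherits(cal, "sip_calibration"))
  if (!labelled$normalized || !control$normalized) {
    stop("classify_otus requires total-sum-scaled tables", call. = FALSE)
  }
  otus <- otu_ids(labelled)
  if (!setequal(otus, otu_ids(control))) {
    stop("labelled and control tables must cover the same OTUs", call. = FALSE)
  }
  windows <- partition_windows(labelled, cal)
  rows <- lapply(otus, function(otu) {
    c1 <- criterion_inter(otu, labelled, control, windows, thr)
    c2 <- criterion_intra(otu, labelled, windows, thr)
    pr <- presence_rule(otu, labelled, control, windows, thr)
    background <- if (pr$applicable) "low" else "high"
    v <- otu_abundance(labelled, otu)
    usable <- !labelled$fractions$missing & !is.na(v)
    peak_density <- if (any(usable)) {
      labelled$fractions$density[usable][which.max(v[usable])]
    } else NA_real_
    status <- "unlabelled"
    if (background == "high" && c1$pass && c2$pass) {
      status <- if (!is.na(peak_density) && peak_density >= cal$strong_density) {
        "strongly_labelled"
      } else "partially_labelled"
    } else if (background == "low" && pr$pass) {
      status <- "present_in_heavy"
    }
    ok <- if (!is.null(gc) && otu %in% names(gc)) {
      gc_confound_check(gc[[otu]], cal$medium, cal)
    } else NA
    if (isFALSE(ok) && status != "unlabelled") {
      warning(sprintf(
        "OTU %s: unlabelled nucleic acid at GC %.2f already bands above the heavy threshold; %s call may be GC-driven",
        otu, gc[[otu]], status))
    }
    tibble::tibble(
      otu_id = otu, status = status, background = background,
      criterion1 = c1$pass, criterion2 = c2$pass, presence = pr$pass,
      peak_density = peak_density,
      heavy_max_pct = c2$evidence[["heavy_max_pct"]],
      light_max_pct = c2$evidence[["light_max_pct"]],
      control_max_pct = c1$evidence[["control_max_pct"]],
      gc_confound_ok = ok
    )
  })
  do.call(rbind, rows)
}
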