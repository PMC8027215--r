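# Pipeline wrappers tying simulation, classification and atom tracing into
# file-in/file-out stages. A thin command-line front end over these
# functions ships in inst/scripts/sip-pipeline.R.

#' Reference synthetic community
#'
#' The default ten-taxon community used throughout the package's examples
#' and recovery checks: low-GC (30 mol%) taxa at equal abundance (10%
#' each), with three tracked taxa at 13C atom fractions 0 (`T_unlab`),
#' 0.4 (`T_partial`, the mixotrophic labelling level) and 1.0
#' (`T_strong`), against seven unlabelled background taxa.
#'
#' @param n_background number of unlabelled background taxa (default 7).
#' @param gc GC fraction shared by all taxa (default 0.30).
#' @return A [community()] tibble.
#' @export
sip_example_community <- function(n_background = 7L, gc = 0.30) {
  ids <- c("T_unlab", "T_partial", "T_strong",
           sprintf("T_bg%02d", seq_len(n_background)))
  community(ids, gc = gc, abundance = 1 / length(ids),
            atom_fraction_13c = c(0, 0.4, 1.0, rep(0, n_background)))
}

#' @rdname sip_example_community
#' @param com a community; returned with every atom fraction set to 0 (the
#'   matching unlabelled control incubation).
#' @export
unlabelled_control <- function(com) {
  com$atom_fraction_13c <- 0
  com
}

#' Read a flat key=value configuration file
#'
#' One `key=value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric.
#'
#' @param path file path.
#' @return Named list.
#' @export
read_sip_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path), call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) {
    stop(sprintf("%s:%d: expected key=value", path, which(bad)[1L]), call. = FALSE)
  }
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, function(p) trimws(p[[1L]]), ""))
}

resolve_config <- function(config, defaults) {
  out <- utils::modifyList(defaults, config[names(config) %in% names(defaults)])
  extra <- setdiff(names(config), names(defaults))
  if (length(extra)) {
    stop(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  out
}

write_manifest <- function(out_dir, stage, config) {
  jsonlite::write_json(c(list(stage = stage), config),
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the simulation stage
#'
#' Simulates a labelled gradient, its unlabelled control, and the pair of
#' calibration standards, and writes them (plus the taxa manifest and a
#' JSON manifest of the resolved configuration) to `out_dir`. Outputs are
#' deterministic for a fixed seed; the control, unlabelled-standard and
#' labelled-standard gradients use seed offsets +1, +2 and +3.
#'
#' Config keys (all optional): `medium` ("dna"/"rna"), `seed`,
#' `read_depth`, `band_sigma`, `template_floor`, `gc_standard`,
#' `label_high`, `taxa` (path of a taxa manifest; default
#' [sip_example_community()]).
#'
#' @param config named list (e.g. from [read_sip_config()]).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the list of written file paths.
#' @export
run_simulate <- function(config = list(), out_dir) {
  cfg <- resolve_config(config, list(
    medium = "dna", seed = 1, read_depth = 50000, band_sigma = 0.004,
    template_floor = 1e-4, gc_standard = 0.51, label_high = 0.99,
    taxa = ""
  ))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  com <- if (nzchar(cfg$taxa)) read_taxa(cfg$taxa) else sip_example_community()
  mk_spec <- function(offset) {
    gradient_spec(cfg$medium, band_sigma = cfg$band_sigma,
                  read_depth = cfg$read_depth,
                  template_floor = cfg$template_floor,
                  seed = offset_seed(cfg$seed, offset))
  }
  labelled <- simulate_gradient(com, mk_spec(0))
  control <- simulate_gradient(unlabelled_control(com), mk_spec(1))
  std <- simulate_standards(mk_spec(2), gc_standard = cfg$gc_standard,
                            label_high = cfg$label_high)
  paths <- file.path(out_dir, c("labelled.tsv", "control.tsv",
                                "standard_unlabelled.tsv",
                                "standard_labelled.tsv", "taxa.tsv"))
  write_fraction_table(labelled, paths[1L])
  write_fraction_table(control, paths[2L])
  write_fraction_table(std$unlabelled, paths[3L])
  write_fraction_table(std$labelled, paths[4L])
  write_taxa(com, paths[5L])
  write_manifest(out_dir, "simulate", cfg)
  invisible(paths)
}

#' Run the classification stage
#'
#' Reads labelled and control fraction tables, calibrates the heavy window
#' (from standard gradients when provided, otherwise the fixed defaults),
#' classifies every OTU and writes `calls.tsv`.
#'
#' Config keys: `labelled`, `control` (paths, required),
#' `standard_unlabelled`, `standard_labelled` (paths, optional), `medium`,
#' `delta_points`, `background_floor`, `taxa` (optional taxa manifest
#' supplying GC for the confound check).
#'
#' @inheritParams run_simulate
#' @return Invisibly, the calls tibble.
#' @export
run_classify <- function(config = list(), out_dir) {
  cfg <- resolve_config(config, list(
    labelled = "", control = "", standard_unlabelled = "",
    standard_labelled = "", medium = "dna", delta_points = 5,
    background_floor = 0.001, taxa = ""
  ))
  if (!nzchar(cfg$labelled) || !nzchar(cfg$control)) {
    stop("config must provide 'labelled' and 'control' table paths", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labelled <- read_fraction_table(cfg$labelled)
  control <- read_fraction_table(cfg$control)
  if (!labelled$normalized) labelled <- total_sum_scale(labelled)
  if (!control$normalized) control <- total_sum_scale(control)
  cal <- if (nzchar(cfg$standard_unlabelled) && nzchar(cfg$standard_labelled)) {
    calibrate(read_fraction_table(cfg$standard_unlabelled),
              read_fraction_table(cfg$standard_labelled), cfg$medium)
  } else {
    fixed_calibration(cfg$medium)
  }
  gc <- NULL
  if (nzchar(cfg$taxa)) {
    taxa <- read_taxa(cfg$taxa)
    gc <- stats::setNames(taxa$gc, taxa$taxon_id)
  }
  calls <- classify_otus(labelled, control, cal,
                         thresholds(cfg$delta_points, cfg$background_floor),
                         gc = gc)
  utils::write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "classify", cfg)
  invisible(calls)
}

#' Run the atom-tracing stage
#'
#' Evaluates a labelling scenario: predicted ribose 13C atom fraction, the
#' implied density shift, and the expected density class.
#'
#' Config keys: `scenario` ("mixotrophy", "lactate" or "autotrophy"),
#' `dic_label`, `substrate_label`, `medium`.
#'
#' @inheritParams run_simulate
#' @param out_dir optional; when given, writes `trace.tsv` and a manifest.
#' @return A one-row tibble: `scenario`, `dic_label`, `ribose_atom_fraction`,
#'   `density_shift`, `predicted_class`.
#' @export
run_trace <- function(config = list(), out_dir = NULL) {
  cfg <- resolve_config(config, list(
    scenario = "mixotrophy", dic_label = 0.99, substrate_label = 0.99,
    medium = "rna"
  ))
  substrate <- switch(cfg$scenario,
    mixotrophy = "unlabelled_polymer",
    lactate = "labelled_lactate",
    autotrophy = "none_autotrophic",
    stop(sprintf("unknown scenario '%s'; use mixotrophy, lactate or autotrophy",
                 cfg$scenario), call. = FALSE)
  )
  sc <- scenario(substrate, dic_label = cfg$dic_label,
                 substrate_label = cfg$substrate_label)
  af <- predict_ribose_label(sc)
  out <- tibble::tibble(
    scenario = cfg$scenario,
    dic_label = cfg$dic_label,
    ribose_atom_fraction = af,
    density_shift = density_shift(af, cfg$medium),
    predicted_class = as.character(predicted_density_class(af, cfg$medium))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(out_dir, "trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "trace", cfg)
  }
  out
}

#' Generate packaged test fixtures
#'
#' Writes a complete, seed-stamped fixture set for the reference community:
#' the simulation outputs of [run_simulate()] plus an `answer_key.tsv` with
#' the expected classification of every taxon (tracked taxa at atom
#' fractions 0 / 0.4 / 1.0 map to unlabelled / partially_labelled /
#' strongly_labelled under the fixed calibration).
#'
#' @param dir output directory.
#' @param size `"tiny"` (read depth 2,000; fast) or `"default"` (50,000).
#' @param seed integer seed.
#' @return Invisibly, the fixture directory.
#' @export
make_fixtures <- function(dir, size = c("tiny", "default"), seed = 1L) {
  size <- match.arg(size)
  depth <- if (size == "tiny") 2000 else 50000
  run_simulate(list(seed = seed, read_depth = depth, medium = "dna"), dir)
  com <- sip_example_community()
  key <- tibble::tibble(
    taxon_id = com$taxon_id,
    atom_fraction_13c = com$atom_fraction_13c,
    expected_status = c("unlabelled", "partially_labelled", "strongly_labelled",
                        rep("unlabelled", nrow(com) - 3L))
  )
  utils::write.table(key, file.path(dir, "answer_key.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
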