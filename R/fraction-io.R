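#' Read and write OTU-by-fraction tables
#'
#' Tables are exchanged as a pair of tab-separated text files: the main
#' table (first column `otu_id`, one column per fraction, header row of
#' fraction ids) and a sidecar metadata file (columns `fraction_id`,
#' `density`, `missing`, `total_mass`, one row per fraction, preceded by a
#' `# normalized=` comment line). Values are written with 17 significant
#' digits so a write/read round trip is lossless. Missing fractions are
#' written as `NA`.
#'
#' @param x a [fraction_table()].
#' @param path path of the main table file.
#' @param meta_path path of the sidecar; defaults to `<path>.meta.tsv`.
#' @return `write_fraction_table()` returns `x` invisibly;
#'   `read_fraction_table()` returns a `fraction_table`.
#' @export
write_fraction_table <- function(x, path, meta_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(x, "fraction_table"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c(
    paste(c("otu_id", x$fractions$fraction_id), collapse = "\t"),
    vapply(seq_len(nrow(x$values)), function(i) {
      paste(c(rownames(x$values)[i], fmt(x$values[i, ])), collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  meta <- c(
    sprintf("# normalized=%s", x$normalized),
    paste(c("fraction_id", "density", "missing", "total_mass"), collapse = "\t"),
    vapply(seq_len(nrow(x$fractions)), function(j) {
      paste(c(x$fractions$fraction_id[j],
              sprintf("%.17g", x$fractions$density[j]),
              as.character(x$fractions$missing[j]),
              fmt(x$fractions$total_mass[j])), collapse = "\t")
    }, "")
  )
  writeLines(meta, meta_path)
  invisible(x)
}

#' @rdname write_fraction_table
#' @export
read_fraction_table <- function(path, meta_path = paste0(path, ".meta.tsv")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (!file.exists(meta_path)) {
    stop(sprintf("sidecar metadata file not found: %s", meta_path), call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop(sprintf("%s: need a header row and at least one OTU row", path), call. = FALSE)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "otu_id") {
    stop(sprintf("%s:1: first header column must be 'otu_id', got '%s'",
                 path, header[1L]), call. = FALSE)
  }
  frac_ids <- header[-1L]
  n_frac <- length(frac_ids)
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != n_frac + 1L) {
      stop(sprintf("%s:%d: expected %d columns, found %d",
                   path, i, n_frac + 1L, length(cells)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(cells[-1L]))
    bad <- which(is.na(vals) & cells[-1L] != "NA")
    if (length(bad)) {
      stop(sprintf("%s:%d: non-numeric value '%s' in column %s",
                   path, i, cells[-1L][bad[1L]], frac_ids[bad[1L]]), call. = FALSE)
    }
    list(id = cells[1L], vals = vals)
  })
  ids <- vapply(rows, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate OTU id '%s'", path, ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  values <- do.call(rbind, lapply(rows, `[[`, "vals"))
  dimnames(values) <- list(ids, frac_ids)

  mlines <- readLines(meta_path)
  normalized <- FALSE
  norm_line <- grep("^# *normalized=", mlines, value = TRUE)
  if (length(norm_line)) normalized <- grepl("TRUE", norm_line[1L], fixed = TRUE)
  mlines <- mlines[!startsWith(mlines, "#")]
  meta <- utils::read.delim(text = paste(mlines, collapse = "\n"),
                            stringsAsFactors = FALSE)
  need <- c("fraction_id", "density", "missing", "total_mass")
  if (!all(need %in% names(meta))) {
    stop(sprintf("%s: sidecar must have columns %s", meta_path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(meta) != n_frac) {
    stop(sprintf("%s: %d metadata rows for %d table columns",
                 meta_path, nrow(meta), n_frac), call. = FALSE)
  }
  if (!identical(as.character(meta$fraction_id), frac_ids)) {
    stop(sprintf("%s: fraction ids disagree with table header", meta_path),
         call. = FALSE)
  }
  if (anyNA(meta$density)) {
    stop(sprintf("%s: missing density for fraction %s", meta_path,
                 meta$fraction_id[which(is.na(meta$density))[1L]]), call. = FALSE)
  }
  fraction_table(values = values,
                 densities = meta$density,
                 fraction_ids = frac_ids,
                 otu_ids = ids,
                 missing = as.logical(meta$missing),
                 total_mass = meta$total_mass,
                 normalized = normalized)
}

#' Write a taxa manifest
#'
#' Writes the community definition (taxon_id, gc, abundance,
#' atom_fraction_13c) as tab-separated text; the companion of the simulated
#' fraction tables.
#'
#' @param community a [community()] data frame.
#' @param path output path.
#' @export
write_taxa <- function(community, path) {
  utils::write.table(community, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(community)
}

#' @rdname write_taxa
#' @export
read_taxa <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  community(df$taxon_id, df$gc, df$abundance, df$atom_fraction_13c)
}
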