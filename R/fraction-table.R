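#' OTU-by-fraction tables
#'
#' A `fraction_table` holds an OTU x gradient-fraction matrix of counts or
#' relative abundances together with per-fraction metadata: buoyant density
#' (g/ml, strictly decreasing with fraction order — fraction 1 is the
#' heaviest, drawn from the bottom of the gradient), a missing flag for
#' fractions that yielded no sequence data, and optionally the total
#' nucleic-acid mass recovered in the fraction. Missing fractions carry `NA`
#' values, never zeros: a failed fraction is not an absent OTU.
#'
#' @param values numeric matrix, OTUs in rows, fractions in columns;
#'   non-negative; columns of missing fractions must be all `NA`.
#' @param densities per-fraction buoyant densities in g/ml, strictly
#'   decreasing.
#' @param fraction_ids,otu_ids identifiers; default to dimnames of `values`.
#' @param missing logical vector flagging failed fractions.
#' @param total_mass per-fraction total nucleic-acid mass (arbitrary units,
#'   e.g. fraction of community mass); `NA` if unknown.
#' @param normalized whether columns are already total-sum scaled.
#' @param counts optional raw count matrix retained alongside scaled values.
#' @return An object of class `fraction_table`.
#' @export
fraction_table <- function(values, densities,
                           fraction_ids = colnames(values),
                           otu_ids = rownames(values),
                           missing = rep(FALSE, length(densities)),
                           total_mass = rep(NA_real_, length(densities)),
                           normalized = FALSE,
                           counts = NULL) {
  values <- as.matrix(values)
  if (is.null(fraction_ids)) fraction_ids <- default_fraction_ids(ncol(values))
  if (is.null(otu_ids)) stop("`otu_ids` (or rownames of `values`) are required", call. = FALSE)
  if (anyDuplicated(otu_ids)) {
    stop(sprintf("duplicate OTU id: %s",
                 paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (length(densities) != ncol(values)) {
    stop(sprintf("%d fraction densities for %d value columns",
                 length(densities), ncol(values)), call. = FALSE)
  }
  if (any(diff(densities) >= 0)) {
    stop("fraction densities must be strictly decreasing (fraction 1 heaviest)",
         call. = FALSE)
  }
  missing <- rep_len(as.logical(missing), ncol(values))
  if (any(values[, !missing, drop = FALSE] < 0, na.rm = TRUE)) {
    stop("fraction table values must be non-negative", call. = FALSE)
  }
  values[, missing] <- NA_real_
  dimnames(values) <- list(as.character(otu_ids), as.character(fraction_ids))
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    dimnames(counts) <- dimnames(values)
  }
  structure(
    list(values = values,
         fractions = data.frame(
           fraction_id = as.character(fraction_ids),
           density = as.numeric(densities),
           missing = missing,
           total_mass = rep_len(as.numeric(total_mass), ncol(values)),
           stringsAsFactors = FALSE
         ),
         normalized = isTRUE(normalized),
         counts = counts),
    class = "fraction_table"
  )
}

#' @export
print.fraction_table <- function(x, ...) {
  cat(sprintf("<fraction_table> %d OTUs x %d fractions (%.4f..%.4f g/ml), %s%s\n",
              nrow(x$values), ncol(x$values),
              max(x$fractions$density), min(x$fractions$density),
              if (x$normalized) "total-sum scaled" else "unnormalized",
              if (any(x$fractions$missing))
                sprintf(", %d missing", sum(x$fractions$missing)) else ""))
  print(utils::head(round(x$values, 4), 6))
  invisible(x)
}

#' @rdname fraction_table
#' @param x a `fraction_table`.
#' @export
otu_ids <- function(x) rownames(x$values)

#' @rdname fraction_table
#' @export
fraction_meta <- function(x) x$fractions

#' Relative abundances of one OTU across fractions
#'
#' @param x a `fraction_table`.
#' @param otu OTU identifier.
#' @return Named numeric vector (NA for missing fractions).
#' @export
otu_abundance <- function(x, otu) {
  if (!otu %in% rownames(x$values)) {
    stop(sprintf("OTU '%s' not present in table", otu), call. = FALSE)
  }
  x$values[otu, ]
}

#' Fraction pooling scheme
#'
#' Defines which gradient fractions are combined before sequencing, as done
#' for RNA-SIP where pairs of fractions (e.g. 4+5, 6+7, 8+9, 10+11) are
#' pooled. Groups must be disjoint; fractions not listed are kept as they
#' are.
#'
#' @param groups named or unnamed list of character vectors of fraction ids.
#' @return An object of class `pooling_scheme`.
#' @export
#' @examples
#' pooling_scheme(list(heavy = c("F04", "F05"), middle = c("F06", "F07"),
#'                     light = c("F08", "F09"), ultra_light = c("F10", "F11")))
pooling_scheme <- function(groups) {
  if (!is.list(groups) || length(groups) == 0L) {
    stop("`groups` must be a non-empty list of fraction id vectors", call. = FALSE)
  }
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids)) {
    stop(sprintf("fraction appears in more than one pooling group: %s",
                 paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- vapply(groups, paste, "", collapse = "+")
  }
  structure(groups, class = "pooling_scheme")
}

#' Standard RNA-SIP pooling of fraction pairs
#'
#' The pooling used for RNA-SIP sequencing: fractions 4+5 (heavy), 6+7
#' (middle), 8+9 (light) and 10+11 (ultra-light) combined; fractions 1-3, 12
#' and 13 left unpooled.
#'
#' @return A [pooling_scheme()].
#' @export
rna_pooling_scheme <- function() {
  pooling_scheme(list(heavy = c("F04", "F05"), middle = c("F06", "F07"),
                      light = c("F08", "F09"), ultra_light = c("F10", "F11")))
}

#' Pool gradient fractions
#'
#' Combines fractions before total-sum scaling: pooled column values are the
#' sums of the member columns' unnormalized values (raw counts when the
#' table retains them), and the pooled density is the arithmetic mean of the
#' member densities. A pooled column is missing if any member is missing.
#' Fractions outside every group pass through unchanged. Columns are
#' reordered by decreasing density.
#'
#' @param x a `fraction_table` with raw counts or unnormalized values.
#' @param scheme a [pooling_scheme()].
#' @return An unnormalized `fraction_table` of pooled columns.
#' @export
pool_fractions <- function(x, scheme) {
  stopifnot(inherits(x, "fraction_table"))
  if (!inherits(scheme, "pooling_scheme")) scheme <- pooling_scheme(scheme)
  src <- if (!is.null(x$counts)) x$counts else x$values
  if (is.null(x$counts) && x$normalized) {
    stop("pooling requires raw counts or unnormalized values; pool before total_sum_scale()",
         call. = FALSE)
  }
  ids <- x$fractions$fraction_id
  unknown <- setdiff(unlist(scheme), ids)
  if (length(unknown)) {
    stop(sprintf("unknown fraction id in pooling scheme: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  leftover <- setdiff(ids, unlist(scheme))
  groups <- c(unclass(scheme), stats::setNames(as.list(leftover), leftover))
  cols <- lapply(groups, function(g) match(g, ids))
  dens <- vapply(cols, function(j) mean(x$fractions$density[j]), 0)
  miss <- vapply(cols, function(j) any(x$fractions$missing[j]), NA)
  mass <- vapply(cols, function(j) sum(x$fractions$total_mass[j]), 0)
  vals <- vapply(cols, function(j) rowSums(src[, j, drop = FALSE]), numeric(nrow(src)))
  if (nrow(src) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(rownames(src), names(groups)))
  ord <- order(dens, decreasing = TRUE)
  fraction_table(values = vals[, ord, drop = FALSE],
                 densities = dens[ord],
                 fraction_ids = names(groups)[ord],
                 otu_ids = rownames(src),
                 missing = miss[ord],
                 total_mass = mass[ord],
                 normalized = FALSE,
                 counts = if (!is.null(x$counts)) vals[, ord, drop = FALSE])
}

#' Total sum scaling
#'
#' Divides each non-missing column by its sum so that per-fraction relative
#' abundances sum to 1. Columns summing to zero are marked missing (no
#' template means no composition). Idempotent on already scaled tables.
#'
#' @param x a `fraction_table` of non-negative counts or abundances.
#' @return A normalized `fraction_table`; raw counts are retained.
#' @export
total_sum_scale <- function(x) {
  stopifnot(inherits(x, "fraction_table"))
  src <- if (!is.null(x$counts)) x$counts else x$values
  if (any(src < 0, na.rm = TRUE)) {
    stop("total_sum_scale requires non-negative values", call. = FALSE)
  }
  vals <- src
  missing <- x$fractions$missing
  for (j in seq_len(ncol(src))) {
    if (missing[j]) { vals[, j] <- NA_real_; next }
    s <- sum(src[, j])
    if (is.na(s) || s == 0) {
      missing[j] <- TRUE
      vals[, j] <- NA_real_
    } else {
      vals[, j] <- src[, j] / s
    }
  }
  fraction_table(values = vals,
                 densities = x$fractions$density,
                 fraction_ids = x$fractions$fraction_id,
                 otu_ids = rownames(src),
                 missing = missing,
                 total_mass = x$fractions$total_mass,
                 normalized = TRUE,
                 counts = if (!is.null(x$counts)) x$counts else src)
}
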