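# Catalogue-level descriptive statistics: discovery time series and
# exponential doubling time, type/phylum distributions, known-product
# (orphan) fraction, and histograms of length, KS count and GC content.

catalog_clusters <- function(catalog) {
  if (inherits(catalog, "pks_catalog")) catalog$clusters else catalog
}

#' Discovery time series of the catalogue
#'
#' Incremental and cumulative cluster counts per calendar year of first
#' deposit. An optional cutoff date drops deposits after the cutoff (used
#' to honour partial final years, e.g. a corpus frozen in August).
#'
#' @param catalog A [pks_catalog()] or list of clusters.
#' @param cutoff Optional `Date` (or ISO string); deposits after it are
#'   excluded.
#' @return Data frame `year, n_new, cumulative` covering every year from
#'   first to last deposit.
#' @export
discovery_timeseries <- function(catalog, cutoff = NULL) {
  clusters <- catalog_clusters(catalog)
  empty <- data.frame(year = integer(), n_new = integer(),
                      cumulative = integer())
  if (!length(clusters)) return(empty)
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  dates <- as.Date(vapply(clusters, function(cl)
    as.character(cl$deposit_date), character(1)))
  if (anyNA(dates)) {
    warning("discovery_timeseries: excluding undated cluster(s): ",
            paste(ids[is.na(dates)], collapse = " "))
    dates <- dates[!is.na(dates)]
  }
  if (!is.null(cutoff)) dates <- dates[dates <= as.Date(cutoff)]
  if (!length(dates)) return(empty)
  yr <- as.integer(format(dates, "%Y"))
  years <- seq(min(yr), max(yr))
  n_new <- vapply(years, function(y) sum(yr == y), integer(1))
  data.frame(year = years, n_new = n_new, cumulative = cumsum(n_new))
}

#' Exponential doubling time of catalogue growth
#'
#' Ordinary least squares of `ln(cumulative)` on year over the years with
#' a positive cumulative count; the doubling time is `ln(2) / slope`.
#'
#' @param timeseries Data frame from [discovery_timeseries()] (columns
#'   `year` and `cumulative`).
#' @return List with `doubling_time_years`, `rate_per_year`, `r_squared`
#'   and `n_years`.
#' @export
doubling_time <- function(timeseries) {
  ts <- timeseries[timeseries$cumulative > 0, , drop = FALSE]
  if (nrow(ts) < 3L)
    stop("doubling_time: need at least 3 years with positive counts")
  if (max(ts$cumulative) == min(ts$cumulative))
    stop("doubling_time: cumulative series is flat")
  if (any(diff(ts$cumulative) < 0))
    stop("doubling_time: cumulative series must be non-decreasing")
  fit <- lm(log(cumulative) ~ year, data = ts)
  slope <- unname(coef(fit)[2])
  if (slope <= 0) stop("doubling_time: non-positive growth rate")
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(doubling_time_years = log(2) / slope, rate_per_year = slope,
       r_squared = r2, n_years = nrow(ts))
}

#' Distribution of assembly-line PKS types
#'
#' @param catalog A [pks_catalog()] or list of classified clusters.
#' @return Data frame `pks_type, count` over the seven-type vocabulary
#'   (zero counts included); counts sum to the catalogue size.
#' @export
type_distribution <- function(catalog) {
  clusters <- catalog_clusters(catalog)
  types <- vapply(clusters, `[[`, "", "pks_type")
  if (anyNA(types))
    stop("type_distribution: unclassified cluster(s) present")
  tab <- table(factor(types, levels = PKS_TYPES))
  data.frame(pks_type = names(tab), count = as.integer(tab),
             row.names = NULL)
}

#' Known-product and orphan fractions
#'
#' @param catalog A [pks_catalog()] or cluster list with `known_product`
#'   flags.
#' @return List `n_total, n_known, known_percent, orphan_percent`.
#' @export
orphan_fraction <- function(catalog) {
  clusters <- catalog_clusters(catalog)
  if (!length(clusters)) stop("orphan_fraction: empty catalogue")
  known <- vapply(clusters, function(cl) isTRUE(cl$known_product),
                  logical(1))
  list(n_total = length(known), n_known = sum(known),
       known_percent = 100 * mean(known),
       orphan_percent = 100 * mean(!known))
}

#' Histogram of a per-cluster metric
#'
#' Metrics: `length_aa` (summed protein lengths), `ks_count` (number of
#' discrete KS domains) and `gc_content` (percent G+C of the cluster
#' nucleotide span). Bins of width `bin_width` anchored at `origin`
#' (defaults to the floor of the data minimum at bin-width resolution)
#' cover the data range exactly; counts sum to the catalogue size.
#' Intervals are left-closed, right-open, except the last which is closed.
#'
#' @param catalog A [pks_catalog()] or cluster list.
#' @param metric `"length_aa"`, `"ks_count"` or `"gc_content"`.
#' @param bin_width Bin width (defaults: 1000 aa, 1 KS, 2 percent).
#' @param origin Optional left edge of the first bin.
#' @return Data frame `bin_start, bin_end, count`.
#' @export
cluster_histogram <- function(catalog, metric = c("length_aa", "ks_count",
                                                  "gc_content"),
                              bin_width = NULL, origin = NULL) {
  metric <- match.arg(metric)
  clusters <- catalog_clusters(catalog)
  if (!length(clusters)) stop("cluster_histogram: empty catalogue")
  x <- switch(metric,
    length_aa = vapply(clusters, cluster_protein_length, numeric(1)),
    ks_count = vapply(clusters, function(cl) as.numeric(nrow(cl$ks_domains)),
                      numeric(1)),
    gc_content = vapply(clusters, cluster_gc_content, numeric(1)))
  if (is.null(bin_width))
    bin_width <- switch(metric, length_aa = 1000, ks_count = 1,
                        gc_content = 2)
  if (is.null(origin)) origin <- floor(min(x) / bin_width) * bin_width
  if (origin > min(x)) stop("cluster_histogram: origin above data minimum")
  edges <- seq(origin, by = bin_width,
               length.out = ceiling((max(x) - origin) / bin_width) + 1L)
  if (max(edges) <= max(x)) edges <- c(edges, max(edges) + bin_width)
  idx <- pmin(findInterval(x, edges), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1L],
             count = counts)
}

#' Distribution of source-organism phyla
#'
#' @param catalog A [pks_catalog()] or cluster list; clusters without a
#'   phylum count as `"unclassified"`.
#' @return Data frame `phylum, count, percent`; percents sum to 100.
#' @export
phylum_distribution <- function(catalog) {
  clusters <- catalog_clusters(catalog)
  if (!length(clusters)) {
    return(data.frame(phylum = character(), count = integer(),
                      percent = numeric()))
  }
  ph <- vapply(clusters, function(cl) {
    p <- cl$phylum
    if (is.na(p) || !nzchar(p)) "unclassified" else p
  }, character(1))
  tab <- sort(table(ph), decreasing = TRUE)
  data.frame(phylum = names(tab), count = as.integer(tab),
             percent = 100 * as.integer(tab) / length(ph),
             row.names = NULL)
}
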