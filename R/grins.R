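# GRINS detection. GRINS (genetic repeats of intense nucleotide skews) are
# roughly 1 kbp segments of a PKS cluster that (i) share atypically high
# DNA identity with another region of the same cluster and (ii) show GC
# and TA skews above 25% in absolute value. Detection therefore combines a
# sliding-window skew profile with k-mer-seeded internal repeat finding.

#' GC skew of a window
#'
#' `(G - C) / (G + C)` over the window; windows without G or C return 0
#' with attribute `degenerate = TRUE`. The skew is antisymmetric under
#' reverse complement.
#'
#' @param window Non-empty DNA string.
#' @return Fraction in `[-1, 1]` (attribute `degenerate` flags a zero
#'   denominator).
#' @export
gc_skew <- function(window) {
  base_skew(window, "G", "C")
}

#' TA skew of a window
#'
#' `(T - A) / (T + A)`; otherwise as [gc_skew()].
#' @inheritParams gc_skew
#' @export
ta_skew <- function(window) {
  base_skew(window, "T", "A")
}

base_skew <- function(window, up, down) {
  if (!nzchar(window)) stop("skew: empty window")
  v <- strsplit(toupper(window), "")[[1]]
  a <- sum(v == up); b <- sum(v == down)
  if (a + b == 0L) return(structure(0, degenerate = TRUE))
  structure((a - b) / (a + b), degenerate = FALSE)
}

#' Sliding-window skew profile
#'
#' Windows of width `window` at starts `0, step, 2*step, ...` while
#' `start + window <= length(seq)`, each scored with [gc_skew()] and
#' [ta_skew()].
#'
#' @param seq DNA string.
#' @param window,step Window width and step in bp.
#' @return Data frame `start, gc_skew, ta_skew, degenerate` with
#'   attributes `window` and `step`. Empty (with a warning) if the
#'   sequence is shorter than one window.
#' @export
skew_profile <- function(seq, window = 150, step = 30) {
  seq <- toupper(seq)
  L <- nchar(seq)
  empty <- structure(
    data.frame(start = integer(), gc_skew = numeric(), ta_skew = numeric(),
               degenerate = logical()),
    window = as.integer(window), step = as.integer(step))
  if (window > L) {
    warning("skew_profile: sequence shorter than one window")
    return(empty)
  }
  v <- strsplit(seq, "")[[1]]
  cg <- cumsum(v == "G"); cc <- cumsum(v == "C")
  ct <- cumsum(v == "T"); ca <- cumsum(v == "A")
  at0 <- function(cs, i) ifelse(i == 0L, 0L, cs[pmax(i, 1L)])
  starts <- seq(0L, L - window, by = step)
  G <- at0(cg, starts + window) - at0(cg, starts)
  C <- at0(cc, starts + window) - at0(cc, starts)
  T_ <- at0(ct, starts + window) - at0(ct, starts)
  A <- at0(ca, starts + window) - at0(ca, starts)
  gc <- ifelse(G + C == 0L, 0, (G - C) / (G + C))
  ta <- ifelse(T_ + A == 0L, 0, (T_ - A) / (T_ + A))
  structure(
    data.frame(start = starts, gc_skew = gc, ta_skew = ta,
               degenerate = (G + C == 0L) | (T_ + A == 0L)),
    window = as.integer(window), step = as.integer(step),
    class = "data.frame")
}

#' Find sustained skewed regions in a profile
#'
#' Maximal runs of step-contiguous windows in which both `|gc_skew|` and
#' `|ta_skew|` reach `min_abs_skew` and each skew keeps a constant sign.
#' Runs whose window-union span is at least `min_region_len` are reported.
#'
#' @param profile Output of [skew_profile()].
#' @param min_abs_skew Minimum absolute skew (default 0.25).
#' @param min_region_len Minimum region span in bp (default 700).
#' @return Data frame `start, end, mean_gc_skew, mean_ta_skew` (0-based
#'   half-open, sequence coordinates).
#' @export
find_skewed_regions <- function(profile, min_abs_skew = 0.25,
                                min_region_len = 700) {
  window <- attr(profile, "window")
  step <- attr(profile, "step")
  empty <- data.frame(start = integer(), end = integer(),
                      mean_gc_skew = numeric(), mean_ta_skew = numeric())
  if (!nrow(profile)) return(empty)
  ok <- abs(profile$gc_skew) >= min_abs_skew &
        abs(profile$ta_skew) >= min_abs_skew & !profile$degenerate
  if (!any(ok)) return(empty)
  idx <- which(ok)
  # split where windows are non-contiguous or a skew flips sign
  brk <- c(TRUE, diff(profile$start[idx]) != step |
                 diff(sign(profile$gc_skew[idx])) != 0 |
                 diff(sign(profile$ta_skew[idx])) != 0)
  run <- cumsum(brk)
  out <- lapply(split(idx, run), function(ii) {
    data.frame(start = profile$start[ii[1]],
               end = profile$start[ii[length(ii)]] + window,
               mean_gc_skew = mean(profile$gc_skew[ii]),
               mean_ta_skew = mean(profile$ta_skew[ii]))
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[res$end - res$start >= min_region_len, , drop = FALSE]
}

# greedy exact extension of an equal-length region pair along its diagonal
extend_pair <- function(v, s1, e1, d) {
  L <- length(v)
  while (s1 > 1L && s1 + d <= L && v[s1 - 1L] == v[s1 - 1L + d]) s1 <- s1 - 1L
  while (e1 + d + 1L <= L && e1 + 1L <= L - d && v[e1 + 1L] == v[e1 + 1L + d])
    e1 <- e1 + 1L
  c(s1, e1)
}

#' Find internal repeats within a cluster sequence
#'
#' Direct (same-strand) repeat pairs are seeded by exact shared 16-mers
#' off the trivial self-diagonal, chained along each diagonal, extended,
#' and scored by per-site identity over the paired spans. Pairs shorter
#' than `min_repeat_len` or below `min_repeat_identity` are discarded;
#' reported pairs never overlap each other.
#'
#' @param seq Cluster DNA string.
#' @param min_repeat_identity Percent identity threshold (default 90).
#' @param min_repeat_len Minimum repeat length in bp (default 700).
#' @param k Seed k-mer size (default 16).
#' @param max_seed_gap Maximum gap between chained seeds on one diagonal
#'   (default 200 bp).
#' @param max_occ Seeds occurring more than this many times (low
#'   complexity) are skipped (default 12).
#' @return Data frame `start1, end1, start2, end2, identity` (0-based
#'   half-open; `start2 > end1` always).
#' @export
find_internal_repeats <- function(seq, min_repeat_identity = 90,
                                  min_repeat_len = 700, k = 16L,
                                  max_seed_gap = 200L, max_occ = 12L) {
  empty <- data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      identity = numeric())
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 2L * min_repeat_len) return(empty)
  v <- strsplit(seq, "")[[1]]
  starts <- 1:(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  occ <- split(starts, kmers)
  occ <- occ[vapply(occ, length, integer(1)) >= 2L]
  if (!length(occ)) return(empty)
  pairs_i <- integer(0); pairs_d <- integer(0)
  for (pos in occ) {
    if (length(pos) > max_occ) next
    pr <- combn(pos, 2L)
    d <- pr[2L, ] - pr[1L, ]
    keep <- d >= min_repeat_len  # copies must not overlap
    pairs_i <- c(pairs_i, pr[1L, keep])
    pairs_d <- c(pairs_d, d[keep])
  }
  if (!length(pairs_i)) return(empty)
  cand <- list()
  for (d in unique(pairs_d)) {
    ii <- sort(unique(pairs_i[pairs_d == d]))
    brk <- c(TRUE, diff(ii) > max_seed_gap)
    for (run in split(ii, cumsum(brk))) {
      s1 <- run[1]; e1 <- run[length(run)] + k - 1L
      ext <- extend_pair(v, s1, e1, d)
      s1 <- ext[1]; e1 <- ext[2]
      span <- e1 - s1 + 1L
      if (span < min_repeat_len || span > d) next
      ident <- 100 * mean(v[s1:e1] == v[(s1 + d):(e1 + d)])
      if (ident < min_repeat_identity) next
      cand[[length(cand) + 1L]] <- data.frame(
        start1 = s1 - 1L, end1 = e1, start2 = s1 + d - 1L, end2 = e1 + d,
        identity = ident)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$end1 - cand$start1), cand$start1), , drop = FALSE]
  # greedy de-overlap: keep longest pairs whose copies don't clash with
  # an already accepted pair on both sides
  accepted <- empty
  for (r in seq_len(nrow(cand))) {
    row <- cand[r, ]
    clash <- FALSE
    if (nrow(accepted)) {
      o1 <- reciprocal_overlap(row$start1, row$end1,
                               accepted$start1, accepted$end1)
      o2 <- reciprocal_overlap(row$start2, row$end2,
                               accepted$start2, accepted$end2)
      clash <- any(o1 >= 0.5 & o2 >= 0.5)
    }
    if (!clash) accepted <- rbind(accepted, row)
  }
  rownames(accepted) <- NULL
  accepted
}

# fraction of the smaller interval covered by the intersection, vectorised
# over the second interval set
reciprocal_overlap <- function(s, e, ss, ee) {
  inter <- pmax(0, pmin(e, ee) - pmax(s, ss))
  pmin_len <- pmin(e - s, ee - ss)
  ifelse(pmin_len > 0, inter / pmin_len, 0)
}

#' Detect GRINS in a cluster
#'
#' A skewed region (from [find_skewed_regions()]) is a GRINS iff it has
#' at least 50% reciprocal overlap with one side of an internal repeat
#' pair (from [find_internal_repeats()]). Both copies of a duplicated
#' skewed segment are reported, each with its partner span and the repeat
#' identity.
#'
#' @param cluster A [pks_cluster()] (or any object with `cluster_id` and
#'   `sequence`).
#' @param params A [grins_params()] object.
#' @return Data frame `cluster_id, start, end, mean_gc_skew, mean_ta_skew,
#'   partner_start, partner_end, repeat_identity` (cluster-relative 0-based
#'   half-open coordinates).
#' @export
detect_grins <- function(cluster, params = grins_params()) {
  empty <- data.frame(cluster_id = character(), start = integer(),
                      end = integer(), mean_gc_skew = numeric(),
                      mean_ta_skew = numeric(), partner_start = integer(),
                      partner_end = integer(), repeat_identity = numeric())
  prof <- skew_profile(cluster$sequence, params$window, params$step)
  regions <- find_skewed_regions(prof, params$min_abs_skew,
                                 params$min_region_len)
  if (!nrow(regions)) return(empty)
  reps <- find_internal_repeats(cluster$sequence,
                                params$min_repeat_identity,
                                params$min_repeat_len)
  if (!nrow(reps)) return(empty)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    best <- NULL
    for (j in seq_len(nrow(reps))) {
      p <- reps[j, ]
      sides <- list(list(s = p$start1, e = p$end1,
                         ps = p$start2, pe = p$end2),
                    list(s = p$start2, e = p$end2,
                         ps = p$start1, pe = p$end1))
      for (side in sides) {
        inter <- max(0, min(r$end, side$e) - max(r$start, side$s))
        if (inter >= 0.5 * (r$end - r$start) &&
            inter >= 0.5 * (side$e - side$s)) {
          if (is.null(best) || p$identity > best$identity)
            best <- list(ps = side$ps, pe = side$pe, identity = p$identity)
        }
      }
    }
    if (!is.null(best)) {
      # a GRINS and its partner are distinct copies; drop degenerate overlaps
      if (min(r$end, best$pe) - max(r$start, best$ps) > 0) next
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = cluster$cluster_id, start = r$start, end = r$end,
        mean_gc_skew = r$mean_gc_skew, mean_ta_skew = r$mean_ta_skew,
        partner_start = best$ps, partner_end = best$pe,
        repeat_identity = best$identity, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' GRINS prevalence by group
#'
#' Per-group share of catalogue clusters carrying at least one GRINS.
#'
#' @param catalog A [pks_catalog()].
#' @param detections Named list: cluster id -> [detect_grins()] data
#'   frame, covering every retained cluster.
#' @param group_by `"pks_type"` or `"phylum"`.
#' @return Data frame `group, n_clusters, n_with_grins, percent`.
#' @export
grins_prevalence <- function(catalog, detections,
                             group_by = c("pks_type", "phylum")) {
  group_by <- match.arg(group_by)
  ids <- names(catalog$clusters)
  if (!all(ids %in% names(detections)))
    stop("grins_prevalence: detections missing for cluster(s): ",
         paste(setdiff(ids, names(detections)), collapse = " "))
  grp <- vapply(catalog$clusters, function(cl) {
    g <- cl[[group_by]]
    if (is.na(g)) "unclassified" else g
  }, character(1))
  has <- vapply(ids, function(id) nrow(detections[[id]]) > 0L, logical(1))
  groups <- sort(unique(grp))
  data.frame(
    group = groups,
    n_clusters = vapply(groups, function(g) sum(grp == g), integer(1)),
    n_with_grins = vapply(groups, function(g) sum(has[grp == g]),
                          integer(1)),
    percent = vapply(groups, function(g)
      100 * sum(has[grp == g]) / sum(grp == g), numeric(1)),
    row.names = NULL)
}

#' Export GRINS detections
#'
#' BED (cluster-relative, 0-based half-open) or TSV with skew and identity
#' columns.
#'
#' @param detections Combined data frame of [detect_grins()] rows.
#' @param path Output file.
#' @param format `"bed"` or `"tsv"`.
#' @export
write_grins <- function(detections, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (is.null(detections) || nrow(detections) == 0L) {
    detections <- data.frame(
      cluster_id = character(), start = integer(), end = integer(),
      mean_gc_skew = numeric(), mean_ta_skew = numeric(),
      partner_start = integer(), partner_end = integer(),
      repeat_identity = numeric())
  }
  if (format == "bed") {
    df <- data.frame(detections$cluster_id, detections$start,
                     detections$end,
                     if (nrow(detections))
                       paste0("GRINS_", seq_len(nrow(detections)))
                     else character(0))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    out <- detections
    for (col in c("mean_gc_skew", "mean_ta_skew", "repeat_identity"))
      out[[col]] <- format_num(out[[col]], 4)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
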