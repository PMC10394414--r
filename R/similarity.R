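# Customized pairwise similarity between assembly lines, redundancy
# pruning, and the rediscovery/novelty statistics built on it. The score
# works at the amino-acid level with local alignments (the domains and
# modules of an assembly line repeat, so global alignment is
# inappropriate) and needs no gene annotation beyond the protein set.

aln_local <- function(a, b, score_only = FALSE) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    scoreOnly = score_only)
}

# Best local alignments between two protein sets, two-phase: a fast
# score-only pass over all pairs, then full alignments only for each
# protein's best partner (the only alignments the score uses).
protein_alignment_table <- function(pa, pb) {
  sc <- matrix(0, length(pa), length(pb))
  for (i in seq_along(pa)) for (j in seq_along(pb))
    sc[i, j] <- aln_local(pa[[i]], pb[[j]], score_only = TRUE)
  need <- unique(rbind(
    cbind(seq_along(pa), apply(sc, 1L, which.max)),
    cbind(apply(sc, 2L, which.max), seq_along(pb))))
  res <- vector("list", nrow(need))
  for (k in seq_len(nrow(need))) {
    i <- need[k, 1L]; j <- need[k, 2L]
    aln <- aln_local(pa[[i]], pb[[j]])
    res[[k]] <- c(i = i, j = j, score = Biostrings::score(aln),
                  identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln),
                  cov_i = Biostrings::width(Biostrings::pattern(aln)),
                  cov_j = Biostrings::width(Biostrings::subject(aln)))
  }
  list(scores = sc, table = as.data.frame(do.call(rbind, res)))
}

directed_score <- function(at, direction, lengths) {
  idx_col <- if (direction == "ab") "i" else "j"
  cov_col <- if (direction == "ab") "cov_i" else "cov_j"
  best_of <- if (direction == "ab") apply(at$scores, 1L, which.max)
             else apply(at$scores, 2L, which.max)
  total <- 0
  for (i in seq_along(lengths)) {
    rows <- if (direction == "ab")
      at$table[at$table$i == i & at$table$j == best_of[i], , drop = FALSE]
    else
      at$table[at$table$j == i & at$table$i == best_of[i], , drop = FALSE]
    if (!nrow(rows)) next
    best <- rows[1L, ]
    total <- total + best$identity * best[[cov_col]]
  }
  100 * total / sum(lengths)
}

#' Pairwise similarity score between two assembly-line clusters
#'
#' Directed score S(a->b): each protein of `a` is locally aligned
#' (BLOSUM62, affine gaps, open 11 / extend 1) against every protein of
#' `b`; its best alignment contributes its identity fraction
#' (matches / alignment columns) multiplied by the number of the protein's
#' residues covered by that alignment. The contributions are summed and
#' divided by the total residue count of `a`. Each query residue is
#' counted at most once (single best alignment per protein). The reported
#' score is the mean of S(a->b) and S(b->a), in percent.
#'
#' Identical clusters score exactly 100; unrelated proteins score close
#' to 0 because their best local alignments are short and cover little.
#'
#' @param a,b [pks_cluster()] objects with non-empty protein sets.
#' @return Percent similarity in `[0, 100]`.
#' @export
pairwise_similarity <- function(a, b) {
  if (!length(a$proteins) || !length(b$proteins))
    stop("pairwise_similarity: cluster without proteins")
  at <- protein_alignment_table(a$proteins, b$proteins)
  s_ab <- directed_score(at, "ab", nchar(a$proteins))
  s_ba <- directed_score(at, "ba", nchar(b$proteins))
  min(100, (s_ab + s_ba) / 2)
}

#' Symmetric similarity matrix over a cluster set
#'
#' Scores every unordered pair once with [pairwise_similarity()]; the
#' diagonal is 100 by definition.
#'
#' @param clusters List of [pks_cluster()] objects (length >= 1).
#' @param verbose Print progress.
#' @return Symmetric numeric matrix with cluster ids as dimnames, entries
#'   in `[0, 100]`, diagonal 100.
#' @export
similarity_matrix <- function(clusters, verbose = FALSE) {
  n <- length(clusters)
  if (n == 0L) stop("similarity_matrix: need at least one cluster")
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- pairwise_similarity(clusters[[i]], clusters[[j]])
      m[i, j] <- s
      m[j, i] <- s
    }
    if (verbose) message("similarity: row ", i, "/", n - 1L)
  }
  m
}

validate_similarity_matrix <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            identical(rownames(m), colnames(m)))
  if (any(m < -tol | m > 100 + tol)) stop("similarity matrix outside [0,100]")
  if (max(abs(m - t(m))) > tol) stop("similarity matrix not symmetric")
  if (any(abs(diag(m) - 100) > tol)) stop("similarity diagonal must be 100")
  invisible(m)
}

#' Write / read a similarity matrix as TSV
#'
#' Square layout: header row of ids, one labelled row per cluster.
#' @param m Similarity matrix.
#' @param path File path.
#' @export
write_similarity_tsv <- function(m, path) {
  df <- data.frame(cluster_id = rownames(m),
                   formatC(m, format = "f", digits = 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cluster_id
  storage.mode(m) <- "double"
  validate_similarity_matrix(m)
}

# pruning priority: earliest deposit date, then longest summed protein
# length, then lexicographic id; undated clusters sort last
prune_priority_order <- function(clusters) {
  dates <- as.numeric(as.Date(vapply(
    clusters, function(cl) as.character(cl$deposit_date), character(1))))
  dates[is.na(dates)] <- Inf
  len <- vapply(clusters, cluster_protein_length, numeric(1))
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  order(dates, -len, ids)
}

#' Remove redundant clusters by similarity threshold
#'
#' Greedy sweep in priority order (earliest deposit date, then longest
#' summed protein length, then lexicographic id): a cluster is retained
#' iff its similarity to every already-retained cluster is at most
#' `threshold`; otherwise it is removed and mapped to the first retained
#' cluster exceeding the threshold. Note the sweep is not transitive: of a
#' chain A~B, B~C with A and C dissimilar, B is removed and both A and C
#' are retained.
#'
#' @param clusters List of [pks_cluster()] objects.
#' @param matrix Similarity matrix covering all cluster ids.
#' @param threshold Redundancy threshold in percent, in (0, 100);
#'   default 90.
#' @return A [pks_catalog()] whose `similarity` is the retained submatrix.
#' @export
remove_redundant <- function(clusters, matrix, threshold = 90) {
  if (!(threshold > 0 && threshold < 100))
    stop("remove_redundant: threshold must be in (0,100)")
  validate_similarity_matrix(matrix)
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  if (!all(ids %in% rownames(matrix)))
    stop("remove_redundant: matrix does not cover all clusters")
  ord <- prune_priority_order(clusters)
  retained_ids <- character(0)
  removed <- character(0)
  for (i in ord) {
    id <- ids[i]
    if (length(retained_ids)) {
      sims <- matrix[id, retained_ids]
      hit <- which(sims > threshold)
      if (length(hit)) {
        removed[id] <- retained_ids[hit[1]]
        next
      }
    }
    retained_ids <- c(retained_ids, id)
  }
  keep <- ids %in% retained_ids
  pks_catalog(clusters[keep], removed,
              matrix[ids[keep], ids[keep], drop = FALSE])
}

#' Cumulative rediscovery-rate time series
#'
#' Clusters are processed in deposit-date order (ties broken by id). A
#' cluster is a rediscovery iff its similarity to *any* earlier cluster
#' exceeds `threshold`. Reported per calendar year as the cumulative
#' percentage of rediscoveries among all clusters deposited so far.
#'
#' @param clusters List of dated [pks_cluster()] objects.
#' @param matrix Similarity matrix covering all cluster ids.
#' @param threshold Percent threshold (default 90).
#' @return Data frame `year, n_total, n_rediscovered, cumulative_percent`.
#' @export
rediscovery_rate <- function(clusters, matrix, threshold = 90) {
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  dates <- as.Date(vapply(clusters, function(cl)
    as.character(cl$deposit_date), character(1)))
  if (anyNA(dates))
    stop("rediscovery_rate: undated cluster(s): ",
         paste(ids[is.na(dates)], collapse = " "))
  validate_similarity_matrix(matrix)
  ord <- order(dates, ids)
  redisc <- logical(length(ord))
  for (k in seq_along(ord)) {
    if (k == 1L) next
    id <- ids[ord[k]]
    earlier <- ids[ord[seq_len(k - 1L)]]
    redisc[k] <- any(matrix[id, earlier] > threshold)
  }
  yr <- as.integer(format(dates[ord], "%Y"))
  years <- sort(unique(yr))
  data.frame(
    year = years,
    n_total = vapply(years, function(y) sum(yr <= y), integer(1)),
    n_rediscovered = vapply(years, function(y) sum(redisc[yr <= y]),
                            integer(1)),
    cumulative_percent = vapply(years, function(y)
      100 * sum(redisc[yr <= y]) / sum(yr <= y), numeric(1)))
}

#' Nearest characterized neighbour of each orphan cluster
#'
#' For each orphan (uncharacterized) cluster, finds the characterized
#' cluster with the maximal similarity score; ties resolve to the
#' lexicographically smaller known id.
#'
#' @param orphan_ids,known_ids Character vectors of cluster ids.
#' @param matrix Similarity matrix covering both sets.
#' @return Data frame `orphan_id, known_id, score`.
#' @export
nearest_characterized <- function(orphan_ids, known_ids, matrix) {
  if (!length(known_ids))
    stop("nearest_characterized: no characterized clusters supplied")
  known_ids <- sort(known_ids)
  rows <- lapply(orphan_ids, function(o) {
    sc <- matrix[o, known_ids]
    best <- which.max(sc)  # first max = lexicographically smallest id
    data.frame(orphan_id = o, known_id = known_ids[best],
               score = unname(sc[best]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Novelty fraction of the orphan set
#'
#' Percent of orphans whose best similarity to any characterized cluster
#' is strictly below `threshold`; such orphans are the candidates most
#' likely to yield novel chemotypes. A score exactly at the threshold
#' counts as NOT novel.
#'
#' @param nearest Data frame from [nearest_characterized()].
#' @param threshold Percent threshold (default 50).
#' @return Percent in `[0, 100]`.
#' @export
novelty_fraction <- function(nearest, threshold = 50) {
  if (!nrow(nearest)) stop("novelty_fraction: empty nearest-neighbour map")
  100 * mean(nearest$score < threshold)
}
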