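# Exact deduplication: the same assembly line frequently enters public
# databases several times (multiple accessions, gene record vs genome
# record, unassembled contigs). Before any similarity scoring, clusters
# that are identical by sequence containment or by domain architecture
# within one species are collapsed to a single representative.

#' Canonical domain-architecture signature of a cluster
#'
#' Per-protein ordered domain-kind tokens joined with `-` within proteins
#' and `|` between proteins, proteins taken in genomic order and domains by
#' amino-acid start. The signature is invariant to the row order of the
#' annotation table and ignores coordinates and protein lengths, so
#' coordinate shifts between duplicate contigs do not break equality.
#'
#' @param cluster A [pks_cluster()].
#' @return Signature string, e.g. `"KS-AT-ACP|KS-AT-KR-ACP-TE"`.
#' @export
architecture_signature <- function(cluster) {
  d <- cluster$domains
  pid <- factor(d$protein_id, levels = names(cluster$proteins))
  parts <- vapply(levels(pid), function(p) {
    rows <- d[d$protein_id == p, , drop = FALSE]
    rows <- rows[order(rows$aa_start), , drop = FALSE]
    paste(rows$kind, collapse = "-")
  }, character(1))
  paste(parts[nzchar(parts)], collapse = "|")
}

#' Are two clusters redundant by nucleotide sequence?
#'
#' TRUE iff one cluster's nucleotide sequence equals, or is an exact
#' substring of, the other's, on either strand. Single-substitution
#' variants are *not* redundant here; they are handled later by similarity
#' scoring.
#'
#' @param a,b [pks_cluster()] objects carrying nucleotide sequence.
#' @return Logical.
#' @export
is_sequence_redundant <- function(a, b) {
  sa <- a$sequence; sb <- b$sequence
  if (nchar(sa) < nchar(sb)) { tmp <- sa; sa <- sb; sb <- tmp }
  grepl(sb, sa, fixed = TRUE) || grepl(revcomp(sb), sa, fixed = TRUE)
}

# representative priority: longest span, then earliest deposit date, then
# lexicographically smallest id
dedup_priority_order <- function(clusters) {
  span <- vapply(clusters, function(cl) cl$end - cl$start, numeric(1))
  dates <- as.numeric(as.Date(vapply(
    clusters, function(cl) as.character(cl$deposit_date), character(1))))
  dates[is.na(dates)] <- Inf
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  order(-span, dates, ids)
}

#' Collapse identical clusters within species
#'
#' Within each species group, clusters equal by [is_sequence_redundant()]
#' *or* by [architecture_signature()] are collapsed (by equivalence
#' closure) to one representative, chosen as the longest span, breaking
#' ties by earliest deposit date and then lexicographic id. Clusters from
#' different species, or with unknown species, are never collapsed.
#'
#' @param clusters List of [pks_cluster()] objects.
#' @return List with `retained` (clusters, input order) and `removed`
#'   (named character vector: removed id -> representative id).
#' @export
dedup_identical <- function(clusters) {
  n <- length(clusters)
  if (n == 0L) return(list(retained = list(), removed = character(0)))
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  species <- tolower(trimws(vapply(clusters, function(cl)
    ifelse(is.na(cl$species), "", cl$species), character(1))))
  sigs <- vapply(clusters, architecture_signature, character(1))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (!nzchar(species[i]) || species[i] != species[j]) next
    if (sigs[i] == sigs[j] || is_sequence_redundant(clusters[[i]], clusters[[j]]))
      union(i, j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  removed <- character(0)
  for (r in unique(roots)) {
    members <- which(roots == r)
    rep_i <- members[dedup_priority_order(clusters[members])[1]]
    keep[rep_i] <- TRUE
    for (m in setdiff(members, rep_i)) removed[ids[m]] <- ids[rep_i]
  }
  list(retained = clusters[keep], removed = removed)
}
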