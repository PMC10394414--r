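# KS-domain mining: translated local-alignment scan of nucleotide records
# against a consensus ketosynthase protein, merging of raw hits into
# discrete KS loci, chaining of loci into candidate assembly lines, and
# cis/trans/hybrid classification of annotated clusters.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# translate one frame (0,1,2) of a plus-strand DNA string; ambiguous codons
# become X, stop codons '*'
translate_frame <- function(seq, frame) {
  L <- nchar(seq)
  n_codons <- (L - frame) %/% 3L
  if (n_codons < 1L) return("")
  sub <- substr(seq, frame + 1L, frame + 3L * n_codons)
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(sub),
                          if.fuzzy.codon = "solve")))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a nucleotide record for KS-domain hits
#'
#' Six-frame translation of the record is locally aligned against a
#' consensus KS protein (affine gaps, BLOSUM62, gap open 11 / extend 1 --
#' the conventional protein-search defaults). Within each frame, maximal
#' non-overlapping alignments are recovered iteratively: the best local
#' alignment is taken, its subject span is masked, and the frame is
#' re-scanned until the score drops below `min_score`. Alignments shorter
#' than `min_len_aa` aligned residues are discarded.
#'
#' @param record An [nt_record()] (length >= 3 nt).
#' @param consensus_ks Consensus KS amino-acid sequence (non-empty string).
#' @param min_score Minimum raw alignment score (BLOSUM62 units). The
#'   default 200 is conservative: a full-length KS match scores in the
#'   thousands while spurious local alignments against random sequence stay
#'   below roughly 60.
#' @param min_len_aa Minimum aligned length in residues (default 150).
#' @return A [ks_hits()] data frame in record coordinates (0-based
#'   half-open, plus strand), sorted by start.
#' @export
scan_ks <- function(record, consensus_ks, min_score = 200, min_len_aa = 150) {
  if (!nzchar(consensus_ks)) stop("scan_ks: empty consensus sequence")
  if (nchar(record$sequence) < 3L) stop("scan_ks: record shorter than 3 nt")
  L <- nchar(record$sequence)
  pat <- Biostrings::AAString(toupper(consensus_ks))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") record$sequence else revcomp(record$sequence)
    for (frame in 0:2) {
      aa <- translate_frame(s, frame)
      if (nchar(aa) < min_len_aa) next
      for (iter in 1:100) {
        aln <- Biostrings::pairwiseAlignment(
          pat, Biostrings::AAString(aa), type = "local",
          substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
        if (Biostrings::score(aln) < min_score) break
        ss <- Biostrings::start(Biostrings::subject(aln))
        se <- Biostrings::end(Biostrings::subject(aln))
        if (Biostrings::nchar(aln) >= min_len_aa) {
          nt0 <- frame + 3L * (ss - 1L)
          nt1 <- frame + 3L * se
          if (strand == "-") { tmp <- nt0; nt0 <- L - nt1; nt1 <- L - tmp }
          out[[length(out) + 1L]] <- data.frame(
            record_id = record$id, start = nt0, end = nt1, strand = strand,
            frame = frame,
            percent_identity =
              100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln),
            score = Biostrings::score(aln), stringsAsFactors = FALSE)
        }
        substr(aa, ss, se) <- strrep("X", se - ss + 1L)
      }
    }
  }
  if (!length(out)) return(empty_hits())
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  ks_hits(df$record_id, df$start, df$end, df$strand, df$frame,
          df$percent_identity, df$score, record_length = L)
}

#' Merge KS hits into discrete KS domains
#'
#' Hits whose inter-interval gap is at most `min_separation` are merged
#' transitively into one KS domain; domains in the output are therefore
#' separated by gaps strictly greater than `min_separation`. Merging is
#' strand-agnostic. This removes multiple hits against one KS and keeps
#' stand-alone KS loci (e.g. fatty-acid synthases) as single domains.
#'
#' @param hits [ks_hits()] rows, all on one record.
#' @param min_separation Gap threshold in bp (default 3000).
#' @return A [ks_domains()] data frame sorted by start.
#' @export
discretize_hits <- function(hits, min_separation = 3000) {
  if (nrow(hits) == 0L) return(ks_domains())
  if (length(unique(hits$record_id)) > 1L)
    stop("discretize_hits: hits span multiple records")
  o <- order(hits$start, hits$end)
  st <- hits$start[o]; en <- hits$end[o]
  cur_s <- st[1]; cur_e <- en[1]; cur_n <- 1L
  res_s <- integer(); res_e <- integer(); res_n <- integer()
  if (length(st) > 1L) for (i in 2:length(st)) {
    if (st[i] - cur_e <= min_separation) {
      cur_e <- max(cur_e, en[i]); cur_n <- cur_n + 1L
    } else {
      res_s <- c(res_s, cur_s); res_e <- c(res_e, cur_e)
      res_n <- c(res_n, cur_n)
      cur_s <- st[i]; cur_e <- en[i]; cur_n <- 1L
    }
  }
  res_s <- c(res_s, cur_s); res_e <- c(res_e, cur_e); res_n <- c(res_n, cur_n)
  ks_domains(rep(hits$record_id[1], length(res_s)), res_s, res_e, res_n)
}

#' Call candidate assembly-line clusters from discrete KS domains
#'
#' KS domains on one record are chained while the gap between consecutive
#' domains is at most `max_gap` (boundary inclusive); chains with at least
#' `min_ks` domains become candidate clusters spanning from the first
#' domain's start to the last domain's end. Chaining (rather than all-pairs
#' proximity) is used so that assembly lines much longer than `max_gap` are
#' still called as single clusters.
#'
#' @param domains A [ks_domains()] data frame (one record).
#' @param max_gap Maximum inter-domain gap in bp (default 20000).
#' @param min_ks Minimum KS domains per cluster (default 3).
#' @return Data frame with `record_id, start, end, n_ks` and a list column
#'   `ks_domains` holding the member [ks_domains()] rows.
#' @export
call_candidate_clusters <- function(domains, max_gap = 20000, min_ks = 3) {
  empty <- data.frame(record_id = character(), start = integer(),
                      end = integer(), n_ks = integer(),
                      stringsAsFactors = FALSE)
  empty$ks_domains <- list()
  if (nrow(domains) == 0L) return(empty)
  if (length(unique(domains$record_id)) > 1L)
    stop("call_candidate_clusters: domains span multiple records")
  o <- order(domains$start, domains$end)
  d <- domains[o, , drop = FALSE]
  gaps <- if (nrow(d) > 1L) d$start[-1L] - d$end[-nrow(d)] else numeric(0)
  chain_id <- cumsum(c(1L, as.integer(gaps > max_gap)))
  out <- list()
  for (cid in unique(chain_id)) {
    members <- d[chain_id == cid, , drop = FALSE]
    if (nrow(members) < min_ks) next
    row <- data.frame(record_id = members$record_id[1],
                      start = members$start[1],
                      end = members$end[nrow(members)],
                      n_ks = nrow(members), stringsAsFactors = FALSE)
    row$ks_domains <- list(members)
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Flatten a cluster's annotations into one ordered domain-kind vector:
# proteins in genomic order (the order of cluster$proteins), domains by
# aa_start within each protein.
ordered_domain_kinds <- function(cluster) {
  d <- cluster$domains
  pid <- factor(d$protein_id, levels = names(cluster$proteins))
  d <- d[order(as.integer(pid), d$aa_start), , drop = FALSE]
  d$kind
}

#' Classify a cluster's assembly-line type
#'
#' Modules are delimited KS-to-next-KS over the cluster's domain
#' annotations taken in protein (genomic) order. A module is cis-AT if an
#' AT domain lies between its KS and the next KS, trans-AT otherwise.
#' NRPS character is the presence of any condensation (C), adenylation (A)
#' or peptidyl-carrier (PCP) domain. The label is the all-cis / all-trans /
#' mixed trichotomy crossed with hybrid status; clusters whose KS modules
#' cannot be typed (no AT anywhere and no ACP anywhere) fall to
#' `"other hybrid"`.
#'
#' @param cluster A [pks_cluster()] with domain annotations.
#' @return One of [pks_types()].
#' @export
classify_cluster <- function(cluster) {
  kinds <- ordered_domain_kinds(cluster)
  ks_pos <- which(kinds == "KS")
  if (length(ks_pos) == 0L)
    stop("classify_cluster: no KS domains annotated")
  hybrid <- any(kinds %in% c("C", "A", "PCP"))
  if (!any(kinds == "AT") && !any(kinds == "ACP")) return("other hybrid")
  bounds <- c(ks_pos, length(kinds) + 1L)
  cis <- vapply(seq_along(ks_pos), function(i) {
    span <- kinds[seq(ks_pos[i], bounds[i + 1L] - 1L)]
    any(span == "AT")
  }, logical(1))
  base <- if (all(cis)) "cis-AT" else if (!any(cis)) "trans-AT" else "mixed cis/trans"
  if (base == "mixed cis/trans") {
    if (hybrid) "mixed cis/trans hybrid" else "mixed cis/trans PKS"
  } else {
    paste0(base, if (hybrid) " PKS-NRPS hybrid" else " PKS")
  }
}
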