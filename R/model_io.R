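# Domain types and readers/writers for the external formats the pipeline
# touches. Internal convention everywhere: 0-based half-open nucleotide and
# amino-acid coordinates on the plus strand; 1-based inclusive external
# dialects (BLAST tabular, domain TSV) are converted at the I/O boundary.

DNA_OK <- c("A", "C", "G", "T", "N")

#' Construct a nucleotide record
#'
#' Carrier for one mined nucleotide entry (a GenBank/WGS-style contig or
#' gene record) together with the metadata the catalogue statistics need.
#'
#' @param id Record identifier (accession-like string).
#' @param sequence DNA string over `A,C,G,T,N`; upper-cased on input.
#' @param species,phylum Optional source-organism labels.
#' @param deposit_date Optional deposit date; anything accepted by
#'   [parse_deposit_date()].
#' @return An object of class `nt_record`.
#' @export
nt_record <- function(id, sequence, species = NA_character_,
                      phylum = NA_character_, deposit_date = NA) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("nt_record: sequence must be non-empty")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), DNA_OK)
  if (length(bad) > 0L) {
    stop("nt_record '", id, "': illegal sequence character(s): ",
         paste(bad, collapse = " "))
  }
  structure(list(id = as.character(id), sequence = sequence,
                 species = species, phylum = phylum,
                 deposit_date = parse_deposit_date(deposit_date)),
            class = "nt_record")
}

#' @export
print.nt_record <- function(x, ...) {
  cat(sprintf("<nt_record> %s (%d bp)%s\n", x$id, nchar(x$sequence),
              if (!is.na(x$species)) paste0(" - ", x$species) else ""))
  invisible(x)
}

#' Parse a deposit date
#'
#' Dates are ISO-8601 (`YYYY-MM-DD`). Year-only values map to July 1 of
#' that year so that year-resolution deposits fall mid-year in the
#' discovery time series.
#'
#' @param x A `Date`, an ISO date string, a bare year, or `NA`.
#' @return A `Date` (possibly `NA`).
#' @export
parse_deposit_date <- function(x) {
  if (length(x) == 0L || all(is.na(x))) return(as.Date(NA))
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)))
  yearly <- grepl("^[0-9]{4}$", x)
  if (any(yearly)) out[yearly] <- as.Date(paste0(x[yearly], "-07-01"))
  full <- !yearly & !is.na(x)
  if (any(full)) out[full] <- as.Date(x[full])
  out
}

#' Read FASTA sequences
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that applies the
#' package's record conventions: the header token before the first
#' whitespace is the id, sequences are upper-cased, and nucleotide records
#' are restricted to the `A,C,G,T,N` alphabet (violations are an error, not
#' silently repaired).
#'
#' @param path FASTA file.
#' @param type `"dna"` (default) returns a list of [nt_record()]s;
#'   `"protein"` returns a named character vector of amino-acid sequences.
#' @return List of `nt_record` or named character vector.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0L) {
    return(if (type == "dna") list() else setNames(character(0), character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicated ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = " "))
  }
  if (type == "protein") return(setNames(unname(seqs), ids))
  lapply(seq_along(ids), function(i) nt_record(ids[i], seqs[i]))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, or a list of [nt_record()]s.
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1]], "nt_record")) {
    seqs <- setNames(vapply(seqs, `[[`, "", "sequence"),
                     vapply(seqs, `[[`, "", "id"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read KS similarity hits from BLAST tabular output
#'
#' Parses the 12-column tabular dialect (`-outfmt 6`). Subject coordinates
#' are 1-based inclusive and reversed for minus-strand hits; they are
#' normalised here to 0-based half-open intervals on the plus strand, with
#' the strand inferred from the coordinate order.
#'
#' @param path BLAST tabular file (no header).
#' @return A `ks_hits` data frame with columns `record_id, start, end,
#'   strand, frame, percent_identity, score`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("read_blast_tab: no such file: ", path)
  if (file.size(path) == 0L) return(empty_hits())
  df <- read.delim(path, header = FALSE, col.names = BLAST6_COLS,
                   stringsAsFactors = FALSE)
  num <- c("sstart", "send", "pident", "bitscore")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop("read_blast_tab: non-numeric '", col, "' field")
    df[[col]] <- v
  }
  minus <- df$send < df$sstart
  start <- ifelse(minus, df$send, df$sstart) - 1L
  end <- ifelse(minus, df$sstart, df$send)
  ks_hits(record_id = df$sseqid, start = start, end = end,
          strand = ifelse(minus, "-", "+"), frame = start %% 3L,
          percent_identity = df$pident, score = df$bitscore)
}

#' Construct a KS hit table
#'
#' @param record_id,start,end,strand,frame,percent_identity,score Parallel
#'   vectors; coordinates 0-based half-open on the plus strand.
#' @param record_length Optional record length used to validate `end`.
#' @return Data frame of class `ks_hits`.
#' @export
ks_hits <- function(record_id = character(), start = integer(),
                    end = integer(), strand = character(),
                    frame = integer(), percent_identity = numeric(),
                    score = numeric(), record_length = NULL) {
  df <- data.frame(record_id = as.character(record_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), frame = as.integer(frame),
                   percent_identity = as.numeric(percent_identity),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$start >= df$end))
      stop("ks_hits: require 0 <= start < end")
    if (!all(df$strand %in% c("+", "-")))
      stop("ks_hits: strand must be '+' or '-'")
    if (!is.null(record_length) && any(df$end > record_length))
      stop("ks_hits: end exceeds record length")
  }
  class(df) <- c("ks_hits", "data.frame")
  df
}

empty_hits <- function() ks_hits()

#' Write KS hits as BLAST tabular
#'
#' Inverse of [read_blast_tab()]: internal 0-based half-open plus-strand
#' intervals become 1-based inclusive subject coordinates, reversed for
#' minus-strand hits, so that a write/read round trip is exact.
#'
#' @param hits `ks_hits` data frame.
#' @param path Output file.
#' @param query Query id written in column 1.
#' @export
write_blast_tab <- function(hits, path, query = "consensus_KS") {
  s1 <- ifelse(hits$strand == "-", hits$end, hits$start + 1L)
  s2 <- ifelse(hits$strand == "-", hits$start + 1L, hits$end)
  alen <- as.integer(round((hits$end - hits$start) / 3))
  df <- data.frame(query, hits$record_id,
                   format_num(hits$percent_identity), alen, 0L, 0L,
                   1L, alen, s1, s2, 0, format_num(hits$score))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# fixed-format numbers so repeated writes are byte-stable
format_num <- function(x, digits = 3L) {
  out <- formatC(x, format = "f", digits = digits)
  sub("\\.?0+$", "", out)
}

#' Construct a table of merged, discrete KS domains
#'
#' @param record_id,start,end,n_source_hits Parallel vectors; merged spans
#'   in 0-based half-open coordinates and the number of raw hits merged
#'   into each.
#' @return Data frame of class `ks_domains`.
#' @export
ks_domains <- function(record_id = character(), start = integer(),
                       end = integer(), n_source_hits = integer()) {
  df <- data.frame(record_id = as.character(record_id),
                   start = as.integer(start), end = as.integer(end),
                   n_source_hits = as.integer(n_source_hits),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$start >= df$end))
      stop("ks_domains: require 0 <= start < end")
    if (any(df$n_source_hits < 1L))
      stop("ks_domains: n_source_hits must be >= 1")
  }
  class(df) <- c("ks_domains", "data.frame")
  df
}

#' Construct a domain-annotation table
#'
#' @param protein_id,kind,aa_start,aa_end Parallel vectors; amino-acid
#'   coordinates 0-based half-open. Kinds outside the vocabulary of
#'   [domain_kinds()] are rejected (readers map them to `"other"` first).
#' @return Data frame of class `domain_annotations`.
#' @export
domain_annotations <- function(protein_id = character(), kind = character(),
                               aa_start = integer(), aa_end = integer()) {
  df <- data.frame(protein_id = as.character(protein_id),
                   kind = as.character(kind),
                   aa_start = as.integer(aa_start),
                   aa_end = as.integer(aa_end), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$kind %in% DOMAIN_KINDS))
      stop("domain_annotations: unknown kind(s): ",
           paste(setdiff(df$kind, DOMAIN_KINDS), collapse = " "))
    if (any(df$aa_start < 0L) || any(df$aa_start >= df$aa_end))
      stop("domain_annotations: require 0 <= aa_start < aa_end")
  }
  class(df) <- c("domain_annotations", "data.frame")
  df
}

#' Read per-protein domain annotations from TSV
#'
#' Expects columns `protein_id, kind, aa_start, aa_end` with 1-based
#' inclusive amino-acid coordinates (the convention of antiSMASH-style
#' domain tables); coordinates are converted to 0-based half-open. Unknown
#' domain kinds are mapped to `"other"` with a warning.
#'
#' @param path TSV file with header.
#' @return `domain_annotations` data frame.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("read_domain_table: no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "kind", "aa_start", "aa_end")
  if (!all(need %in% names(df)))
    stop("read_domain_table: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = " "))
  if (nrow(df) == 0L) return(domain_annotations())
  for (col in c("aa_start", "aa_end")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v)) stop("read_domain_table: non-numeric '", col, "'")
    df[[col]] <- v
  }
  if (any(df$aa_start > df$aa_end))
    stop("read_domain_table: aa_start > aa_end")
  unknown <- !(df$kind %in% DOMAIN_KINDS)
  if (any(unknown)) {
    warning("read_domain_table: unknown domain kind(s) mapped to 'other': ",
            paste(unique(df$kind[unknown]), collapse = " "))
    df$kind[unknown] <- "other"
  }
  domain_annotations(df$protein_id, df$kind, df$aa_start - 1L, df$aa_end)
}

#' Write domain annotations as TSV
#'
#' Inverse of [read_domain_table()] (1-based inclusive on disk).
#' @param domains `domain_annotations` data frame.
#' @param path Output file.
#' @export
write_domain_table <- function(domains, path) {
  out <- data.frame(protein_id = domains$protein_id, kind = domains$kind,
                    aa_start = domains$aa_start + 1L,
                    aa_end = domains$aa_end, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mining parameters
#'
#' Bundles the thresholds of the cluster-calling and redundancy pipeline:
#' `min_separation` (bp gap below which KS hits merge into one domain,
#' default 3000), `max_gap` (bp chaining distance between KS domains of one
#' assembly line, default 20000), `min_ks` (minimum KS domains per cluster,
#' default 3), `redundancy_threshold` (percent similarity above which two
#' clusters are redundant, default 90), `network_threshold` (percent
#' similarity above which network edges are drawn, default 50) and a
#' [grins_params()] object.
#'
#' @param min_separation,max_gap,min_ks,redundancy_threshold,network_threshold
#'   See description.
#' @param grins A [grins_params()] list.
#' @return List of class `mining_params`.
#' @export
mining_params <- function(min_separation = 3000, max_gap = 20000,
                          min_ks = 3, redundancy_threshold = 90,
                          network_threshold = 50, grins = grins_params()) {
  p <- list(min_separation = min_separation, max_gap = max_gap,
            min_ks = as.integer(min_ks),
            redundancy_threshold = redundancy_threshold,
            network_threshold = network_threshold, grins = grins)
  stopifnot(min_separation > 0, max_gap > 0, min_ks > 0,
            redundancy_threshold > 0, network_threshold > 0)
  if (!(network_threshold < redundancy_threshold))
    stop("mining_params: network_threshold must be < redundancy_threshold")
  structure(p, class = "mining_params")
}

#' GRINS detection parameters
#'
#' @param window Sliding-window width in bp for skew profiles (default 150).
#' @param step Window step in bp (default 30).
#' @param min_abs_skew Minimum absolute GC and TA skew of a candidate
#'   region (default 0.25).
#' @param min_region_len Minimum skewed-region span in bp (default 700;
#'   operationalises "approximately 1 kbp").
#' @param target_region_len Reporting-only nominal region length (1000).
#' @param min_repeat_identity Minimum percent identity of the internal
#'   repeat pair (default 90).
#' @param min_repeat_len Minimum repeat length in bp (default 700).
#' @return List of class `grins_params`.
#' @export
grins_params <- function(window = 150, step = 30, min_abs_skew = 0.25,
                         min_region_len = 700, target_region_len = 1000,
                         min_repeat_identity = 90, min_repeat_len = 700) {
  if (window < step) stop("grins_params: window must be >= step")
  if (!(min_abs_skew > 0 && min_abs_skew < 1))
    stop("grins_params: min_abs_skew must be in (0,1)")
  structure(list(window = as.integer(window), step = as.integer(step),
                 min_abs_skew = min_abs_skew,
                 min_region_len = as.integer(min_region_len),
                 target_region_len = as.integer(target_region_len),
                 min_repeat_identity = min_repeat_identity,
                 min_repeat_len = as.integer(min_repeat_len)),
            class = "grins_params")
}

#' Construct an assembly-line PKS cluster
#'
#' The catalogue unit: a candidate assembly line with its nucleotide span,
#' proteins, domain annotations, classification and provenance metadata.
#'
#' @param cluster_id,record_id Identifiers.
#' @param start,end Nucleotide span on the source record (0-based
#'   half-open).
#' @param sequence Nucleotide sequence of the span.
#' @param ks_domains A [ks_domains()] table (record coordinates).
#' @param proteins Named character vector of amino-acid sequences, ordered
#'   by genomic position.
#' @param domains A [domain_annotations()] table; every `protein_id` must
#'   occur in `proteins`.
#' @param pks_type One of [pks_types()] or `NA` before classification.
#' @param species,phylum,deposit_date,known_product Metadata.
#' @param min_ks Minimum number of KS domains (default 3).
#' @return Object of class `pks_cluster`.
#' @export
pks_cluster <- function(cluster_id, record_id, start, end, sequence,
                        ks_domains, proteins, domains,
                        pks_type = NA_character_, species = NA_character_,
                        phylum = NA_character_, deposit_date = NA,
                        known_product = FALSE, min_ks = 3L) {
  if (nrow(ks_domains) < min_ks)
    stop("pks_cluster '", cluster_id, "': fewer than ", min_ks,
         " KS domains")
  if (nrow(domains) && !all(domains$protein_id %in% names(proteins)))
    stop("pks_cluster '", cluster_id,
         "': domain annotations reference unknown protein(s)")
  if (!is.na(pks_type) && !(pks_type %in% PKS_TYPES))
    stop("pks_cluster: unknown pks_type '", pks_type, "'")
  structure(list(cluster_id = as.character(cluster_id),
                 record_id = as.character(record_id),
                 start = as.integer(start), end = as.integer(end),
                 sequence = toupper(sequence), ks_domains = ks_domains,
                 proteins = proteins, domains = domains,
                 pks_type = pks_type, species = species, phylum = phylum,
                 deposit_date = parse_deposit_date(deposit_date),
                 known_product = isTRUE(known_product)),
            class = "pks_cluster")
}

#' @export
print.pks_cluster <- function(x, ...) {
  cat(sprintf("<pks_cluster> %s: %d bp, %d KS, %d proteins, type %s\n",
              x$cluster_id, x$end - x$start, nrow(x$ks_domains),
              length(x$proteins),
              ifelse(is.na(x$pks_type), "?", x$pks_type)))
  invisible(x)
}

cluster_protein_length <- function(cl) sum(nchar(cl$proteins))

cluster_gc_content <- function(cl) {
  v <- strsplit(cl$sequence, "")[[1]]
  100 * sum(v %in% c("G", "C")) / sum(v %in% c("A", "C", "G", "T"))
}

#' Construct a catalogue
#'
#' A non-redundant cluster set plus the map from removed cluster ids to
#' their retained representatives and (optionally) the similarity matrix
#' over the retained set.
#'
#' @param clusters List of [pks_cluster()] objects (retained set).
#' @param removed Named character vector: removed id -> retained id.
#' @param similarity Optional [similarity_matrix()] over the retained ids.
#' @return Object of class `pks_catalog`.
#' @export
pks_catalog <- function(clusters, removed = character(0), similarity = NULL) {
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  names(clusters) <- ids
  if (length(removed)) {
    if (is.null(names(removed)) || any(!nzchar(names(removed))))
      stop("pks_catalog: removed map must be named")
    if (!all(removed %in% ids))
      stop("pks_catalog: removed ids must map to retained ids")
    if (any(names(removed) %in% ids))
      stop("pks_catalog: a cluster cannot be both removed and retained")
  }
  if (!is.null(similarity) && !setequal(rownames(similarity), ids))
    stop("pks_catalog: similarity matrix ids do not match clusters")
  structure(list(clusters = clusters, removed = removed,
                 similarity = similarity),
            class = "pks_catalog")
}

#' @export
print.pks_catalog <- function(x, ...) {
  cat(sprintf("<pks_catalog> %d retained cluster(s), %d removed\n",
              length(x$clusters), length(x$removed)))
  invisible(x)
}

#' @export
length.pks_catalog <- function(x) length(x$clusters)

catalog_summary_df <- function(catalog) {
  rows <- lapply(catalog$clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, species = cl$species,
               phylum = cl$phylum, pks_type = cl$pks_type,
               length_aa = cluster_protein_length(cl),
               ks_count = nrow(cl$ks_domains),
               gc_content = cluster_gc_content(cl),
               deposit_date = as.character(cl$deposit_date),
               known_product = cl$known_product, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(cluster_id = character(), species = character(),
                      phylum = character(), pks_type = character(),
                      length_aa = integer(), ks_count = integer(),
                      gc_content = numeric(), deposit_date = character(),
                      known_product = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a catalogue summary
#'
#' One row (TSV) or object (JSON) per retained cluster with id, species,
#' phylum, type, summed protein length, KS count, GC content, deposit date
#' and known-product flag. Round-trips through [read_catalog()].
#'
#' @param catalog A [pks_catalog()].
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_catalog <- function(catalog, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- catalog_summary_df(catalog)
  df$gc_content <- round(df$gc_content, 4)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a catalogue summary written by [write_catalog()]
#'
#' @param path File written by [write_catalog()].
#' @param format `"tsv"` or `"json"`.
#' @return Data frame of per-cluster summary rows.
#' @export
read_catalog <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(deposit_date = "character"))
  } else {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0L) df <- catalog_summary_df(pks_catalog(list()))
  }
  df
}
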