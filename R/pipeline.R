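# End-to-end pipeline: scan/ingest -> discretize -> cluster -> classify ->
# dedup -> similarity -> prune -> network/dendrogram -> GRINS -> stats.
# Every artefact is written as deterministic text so repeated runs on
# identical inputs are byte-stable.

#' Assemble pipeline configuration
#'
#' @param genome_fasta Nucleotide FASTA of records to mine.
#' @param proteins_faa Protein FASTA (ids must match the locations table).
#' @param protein_locations_tsv TSV `protein_id, record_id, start, end,
#'   strand` (0-based half-open record coordinates).
#' @param domain_tsv Domain-annotation TSV (see [read_domain_table()]).
#' @param metadata_tsv Optional TSV `record_id, species, phylum,
#'   deposit_date, known_product`.
#' @param consensus_faa Consensus KS protein FASTA (used when `hits_tsv`
#'   is not given).
#' @param hits_tsv Optional precomputed BLAST tabular KS hits; skips the
#'   built-in scanner.
#' @param out_dir Output directory (created).
#' @param params A [mining_params()] object.
#' @param min_score,min_len_aa Scanner thresholds (see [scan_ks()]).
#' @param cutoff Optional deposit-date cutoff for the discovery series.
#' @param seed Integer seed echoed into the resolved configuration.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, proteins_faa,
                            protein_locations_tsv, domain_tsv,
                            metadata_tsv = NULL, consensus_faa = NULL,
                            hits_tsv = NULL, out_dir = "pksminer_out",
                            params = mining_params(), min_score = 200,
                            min_len_aa = 150, cutoff = NULL, seed = 1L) {
  if (is.null(consensus_faa) && is.null(hits_tsv))
    stop("pipeline_config: need consensus_faa or hits_tsv")
  structure(list(genome_fasta = genome_fasta, proteins_faa = proteins_faa,
                 protein_locations_tsv = protein_locations_tsv,
                 domain_tsv = domain_tsv, metadata_tsv = metadata_tsv,
                 consensus_faa = consensus_faa, hits_tsv = hits_tsv,
                 out_dir = out_dir, params = params, min_score = min_score,
                 min_len_aa = min_len_aa, cutoff = cutoff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

read_protein_locations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "record_id", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("protein locations: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = " "))
  df
}

read_record_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(deposit_date = "character"))
  if (!"record_id" %in% names(df))
    stop("metadata: missing record_id column")
  df
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full mining pipeline
#'
#' Executes every stage on the configured inputs and writes all artefacts
#' (hit/domain/candidate tables, catalogue TSV+JSON, similarity matrix,
#' GraphML/SIF/edge-list network, Newick dendrogram, GRINS table,
#' statistics JSON) plus a manifest of per-stage counts and the resolved
#' configuration into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage progress.
#' @return Invisibly, a list with the catalogue, similarity matrix,
#'   network, GRINS detections, statistics and the manifest.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  t_start <- Sys.time()
  log_msg <- function(...) if (verbose) message("[pksminer] ", ...)
  params <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  records <- stage("read_genomes", read_fasta(config$genome_fasta, "dna"))
  names(records) <- vapply(records, `[[`, "", "id")
  proteins <- stage("read_proteins", read_fasta(config$proteins_faa,
                                                "protein"))
  locations <- stage("read_locations",
                     read_protein_locations(config$protein_locations_tsv))
  if (is.null(config$domain_tsv) || !file.exists(config$domain_tsv))
    stop("pipeline stage 'read_domains' failed: domain table required (",
         if (is.null(config$domain_tsv)) "none given"
         else config$domain_tsv, ")", call. = FALSE)
  domains <- stage("read_domains", read_domain_table(config$domain_tsv))
  meta <- NULL
  if (!is.null(config$metadata_tsv))
    meta <- stage("read_metadata", read_record_metadata(config$metadata_tsv))
  log_msg(length(records), " record(s), ", length(proteins), " protein(s)")

  # stage 1: KS hits
  hits <- stage("ks_hits", {
    if (!is.null(config$hits_tsv)) {
      read_blast_tab(config$hits_tsv)
    } else {
      cons <- read_fasta(config$consensus_faa, "protein")[[1]]
      do.call(rbind, lapply(records, scan_ks, consensus_ks = cons,
                            min_score = config$min_score,
                            min_len_aa = config$min_len_aa))
    }
  })
  write_blast_tab(hits, out("ks_hits.tsv"))
  log_msg(nrow(hits), " KS hit(s)")

  # stage 2: discrete KS domains, then candidate clusters per record
  ks_doms <- stage("discretize", {
    parts <- lapply(split(seq_len(nrow(hits)), hits$record_id),
                    function(ii) discretize_hits(hits[ii, , drop = FALSE],
                                                 params$min_separation))
    if (!length(parts)) ks_domains()
    else do.call(rbind, c(parts, list(make.row.names = FALSE)))
  })
  write.table(ks_doms, out("ks_domains.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cands <- stage("call_clusters", {
    parts <- lapply(split(seq_len(nrow(ks_doms)), ks_doms$record_id),
                    function(ii) call_candidate_clusters(
                      ks_doms[ii, , drop = FALSE],
                      params$max_gap, params$min_ks))
    if (!length(parts)) call_candidate_clusters(ks_domains())
    else do.call(rbind, c(parts, list(make.row.names = FALSE)))
  })
  write.table(cands[, c("record_id", "start", "end", "n_ks")],
              out("candidate_clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_msg(nrow(ks_doms), " discrete KS, ", nrow(cands), " candidate(s)")

  # stage 3: assemble cluster objects (proteins, domains, metadata)
  clusters <- stage("assemble", {
    res <- list()
    for (i in seq_len(nrow(cands))) {
      rid <- cands$record_id[i]
      loc <- locations[locations$record_id == rid &
                       locations$end > cands$start[i] &
                       locations$start < cands$end[i], , drop = FALSE]
      if (!nrow(loc)) next
      loc <- loc[order(loc$start), , drop = FALSE]
      prot <- proteins[loc$protein_id]
      dom <- domains[domains$protein_id %in% loc$protein_id, , drop = FALSE]
      md <- list(species = NA, phylum = NA, deposit_date = NA,
                 known_product = FALSE)
      if (!is.null(meta) && rid %in% meta$record_id) {
        row <- meta[meta$record_id == rid, ]
        for (f in intersect(names(md), names(row))) md[[f]] <- row[[f]]
      }
      id <- sprintf("%s_c%02d", rid, sum(cands$record_id[seq_len(i)] == rid))
      kd <- cands$ks_domains[[i]]
      res[[id]] <- pks_cluster(
        id, rid, cands$start[i], cands$end[i],
        substr(records[[rid]]$sequence, cands$start[i] + 1L, cands$end[i]),
        kd, prot, dom, species = md$species, phylum = md$phylum,
        deposit_date = md$deposit_date,
        known_product = isTRUE(md$known_product) ||
          identical(md$known_product, "TRUE"),
        min_ks = params$min_ks)
    }
    res
  })
  clusters <- stage("classify", lapply(clusters, function(cl) {
    cl$pks_type <- classify_cluster(cl)
    cl
  }))
  log_msg(length(clusters), " assembled cluster(s)")

  # stage 4: exact deduplication
  dd <- stage("dedup", dedup_identical(unname(clusters)))
  log_msg(length(dd$retained), " after dedup (", length(dd$removed),
          " removed)")

  # stage 5: similarity matrix
  simmat <- stage("similarity", similarity_matrix(dd$retained))
  write_similarity_tsv(simmat, out("similarity.tsv"))

  # stage 6: redundancy pruning
  catalog <- stage("prune", remove_redundant(dd$retained, simmat,
                                             params$redundancy_threshold))
  log_msg(length(catalog$clusters), " retained after ",
          params$redundancy_threshold, "% pruning")
  write_catalog(catalog, out("catalog.tsv"), "tsv")
  write_catalog(catalog, out("catalog.json"), "json")
  removed_all <- c(dd$removed, catalog$removed)
  removed_df <- data.frame(removed_id = as.character(names(removed_all)),
                           representative_id = unname(removed_all),
                           stringsAsFactors = FALSE)
  write.table(removed_df[order(removed_df$removed_id), , drop = FALSE],
              out("removed_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # stage 7: network + dendrogram
  node_attrs <- catalog_summary_df(catalog)[
    , c("cluster_id", "pks_type", "phylum", "known_product")]
  net <- stage("network", build_network(catalog$similarity,
                                        params$network_threshold,
                                        node_attrs))
  export_network(net, out("network.graphml"), "graphml")
  export_network(net, out("network.sif"), "sif")
  export_network(net, out("network_edges.tsv"), "edge_tsv")
  comps <- connected_components(net)
  if (length(catalog$clusters) >= 2L)
    write_dendrogram(build_dendrogram(catalog$similarity),
                     out("dendrogram.nwk"))

  # stage 8: GRINS
  grins <- stage("grins", lapply(catalog$clusters, detect_grins,
                                 params = params$grins))
  grins_all <- do.call(rbind, c(unname(grins), list(make.row.names = FALSE)))
  write_grins(grins_all, out("grins.tsv"), "tsv")
  write_grins(grins_all, out("grins.bed"), "bed")
  grins_prev <- list(
    by_type = grins_prevalence(catalog, grins, "pks_type"),
    by_phylum = grins_prevalence(catalog, grins, "phylum"))

  # stage 9: statistics
  stats <- stage("stats", {
    ts <- discovery_timeseries(catalog, cutoff = config$cutoff)
    dt <- tryCatch(doubling_time(ts), error = function(e) NULL)
    list(timeseries = ts, doubling = dt,
         type_distribution = type_distribution(catalog),
         orphan = orphan_fraction(catalog),
         phylum_distribution = phylum_distribution(catalog),
         hist_length_aa = cluster_histogram(catalog, "length_aa"),
         hist_ks_count = cluster_histogram(catalog, "ks_count"),
         hist_gc = cluster_histogram(catalog, "gc_content"),
         grins_prevalence = grins_prev)
  })
  jsonlite::write_json(stats, out("stats.json"), auto_unbox = TRUE,
                       digits = 10, na = "null", pretty = TRUE)

  manifest <- list(
    n_records = length(records), n_hits = nrow(hits),
    n_ks_domains = nrow(ks_doms), n_candidates = nrow(cands),
    n_assembled = length(clusters), n_after_dedup = length(dd$retained),
    n_removed_dedup = length(dd$removed),
    n_retained = length(catalog$clusters),
    n_removed_redundant = length(catalog$removed),
    n_network_edges = igraph::ecount(net),
    n_network_components = length(comps$components),
    n_disconnected = length(comps$disconnected),
    n_clusters_with_grins =
      sum(vapply(grins, nrow, integer(1)) > 0L))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  cfg_echo <- config
  cfg_echo$params <- unclass(cfg_echo$params)
  cfg_echo$params$grins <- unclass(cfg_echo$params$grins)
  yaml::write_yaml(unclass(cfg_echo), out("config.yaml"))
  log_msg("done in ", format(round(difftime(Sys.time(), t_start,
                                            units = "secs"), 1)))
  invisible(list(catalog = catalog, similarity = simmat, network = net,
                 components = comps, grins = grins, stats = stats,
                 manifest = manifest))
}

#' Write a synthetic corpus to disk
#'
#' Serialises a [generate_catalog()] result into the file set
#' [run_pipeline()] consumes: genome FASTA, protein FASTA, protein
#' locations TSV, domain TSV, record metadata TSV, the consensus KS FASTA
#' and a truth manifest JSON.
#'
#' @param cat Output of [generate_catalog()].
#' @param dir Output directory (created).
#' @return Named list of file paths, invisibly.
#' @export
write_synthetic_corpus <- function(cat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gens <- cat$generated
  paths <- list(
    genome_fasta = file.path(dir, "genomes.fna"),
    proteins_faa = file.path(dir, "proteins.faa"),
    protein_locations_tsv = file.path(dir, "protein_locations.tsv"),
    domain_tsv = file.path(dir, "domains.tsv"),
    metadata_tsv = file.path(dir, "metadata.tsv"),
    consensus_faa = file.path(dir, "consensus_ks.faa"),
    truth_json = file.path(dir, "truth.json"))
  write_fasta(lapply(gens, `[[`, "record"), paths$genome_fasta)
  prot <- unlist(unname(lapply(gens, `[[`, "proteins")))
  write_fasta(prot, paths$proteins_faa)
  loc <- do.call(rbind, c(lapply(gens, `[[`, "locations"),
                          list(make.row.names = FALSE)))
  write.table(loc, paths$protein_locations_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  dom <- do.call(rbind, c(lapply(gens, `[[`, "domains"),
                          list(make.row.names = FALSE)))
  write_domain_table(dom, paths$domain_tsv)
  md <- do.call(rbind, lapply(gens, function(g) data.frame(
    record_id = g$record$id, species = g$record$species,
    phylum = g$record$phylum,
    deposit_date = as.character(g$record$deposit_date),
    known_product = g$cluster$known_product, stringsAsFactors = FALSE)))
  write.table(md, paths$metadata_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fasta(c(consensus_KS = synthetic_consensus_ks()),
              paths$consensus_faa)
  truth <- list(
    n_clusters = length(gens),
    cluster_ids = names(gens),
    family = as.list(cat$truth$family),
    redundant_ids = cat$truth$redundant_ids,
    duplicate_ids = cat$truth$duplicate_ids,
    known_ids = cat$truth$known_ids,
    n_families = cat$truth$n_families,
    ks_per_cluster = lapply(gens, function(g) nrow(g$truth$ks_nt)))
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
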