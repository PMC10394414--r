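# Shared fixtures and independent brute-force oracles. Oracles are kept
# deliberately naive (exhaustive enumeration, boolean-matrix closure) and
# independent of the package's algorithms.

# minimal cluster stub for operations that only touch a few fields;
# bypasses the constructor on purpose (tests that need validation use
# pks_cluster() directly)
stub_cluster <- function(cluster_id, sequence = "ACGT",
                         proteins = c(p1 = "MKLV"),
                         domains = NULL, species = "Genus species",
                         phylum = NA_character_, deposit_date = NA,
                         known_product = FALSE, pks_type = NA_character_,
                         start = 0L, end = nchar(sequence)) {
  if (is.null(domains)) domains <- domain_annotations()
  structure(list(cluster_id = cluster_id, record_id = cluster_id,
                 start = start, end = end, sequence = sequence,
                 ks_domains = ks_domains(), proteins = proteins,
                 domains = domains, pks_type = pks_type,
                 species = species, phylum = phylum,
                 deposit_date = parse_deposit_date(deposit_date),
                 known_product = known_product),
            class = "pks_cluster")
}

# a cluster with explicit per-protein domain-kind lists (coordinates are
# synthesized); for signature/classification tests
arch_cluster <- function(cluster_id, arch, species = "Genus species",
                         sequence = NULL, deposit_date = NA,
                         seq_len_per_prot = 120L) {
  proteins <- character(0)
  rows <- list()
  for (p in seq_along(arch)) {
    pid <- sprintf("%s_p%d", cluster_id, p)
    kinds <- arch[[p]]
    len <- 50L * length(kinds) + 10L
    proteins[pid] <- strrep("M", len)
    for (d in seq_along(kinds)) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, kind = kinds[d], aa_start = 50L * (d - 1L),
        aa_end = 50L * d, stringsAsFactors = FALSE)
    }
  }
  dd <- do.call(rbind, rows)
  if (is.null(sequence))
    sequence <- paste(rep(c("A", "C", "G", "T"), length.out = 400L),
                      collapse = "")
  stub_cluster(cluster_id, sequence = sequence, proteins = proteins,
               domains = domain_annotations(dd$protein_id, dd$kind,
                                            dd$aa_start, dd$aa_end),
               species = species, deposit_date = deposit_date)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- oracles ------------------------------------------------------------

# transitive interval merging by exhaustive pair closure
oracle_merge_hits <- function(st, en, min_sep) {
  n <- length(st)
  if (n == 0L) return(data.frame(start = integer(), end = integer(),
                                 n = integer()))
  adj <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    gap <- max(st[i], st[j]) - min(en[i], en[j])
    adj[i, j] <- gap <= min_sep
  }
  reach <- adj
  for (k in 1:n) reach <- reach | (reach %*% reach > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in 1:n) if (is.na(comp[i])) {
    cid <- cid + 1L
    comp[which(reach[i, ])] <- cid
  }
  out <- do.call(rbind, lapply(unique(comp[order(st)]), function(cc) {
    data.frame(start = min(st[comp == cc]), end = max(en[comp == cc]),
               n = sum(comp == cc))
  }))
  out[order(out$start), , drop = FALSE]
}

# chain enumeration for cluster calling: all maximal runs of sorted
# domains with consecutive gaps <= max_gap
oracle_call_clusters <- function(st, en, max_gap, min_ks) {
  o <- order(st, en)
  st <- st[o]; en <- en[o]
  n <- length(st)
  if (n == 0L) return(data.frame(start = integer(), end = integer(),
                                 n_ks = integer()))
  runs <- list(); cur <- 1L
  if (n > 1L) for (i in 2:n) {
    if (st[i] - en[i - 1L] > max_gap) {
      runs[[length(runs) + 1L]] <- cur:(i - 1L)
      cur <- i
    }
  }
  runs[[length(runs) + 1L]] <- cur:n
  keep <- Filter(function(r) length(r) >= min_ks, runs)
  if (!length(keep)) return(data.frame(start = integer(), end = integer(),
                                       n_ks = integer()))
  do.call(rbind, lapply(keep, function(r) data.frame(
    start = st[r[1]], end = en[r[length(r)]], n_ks = length(r))))
}

# equivalence closure of an arbitrary pair predicate via boolean matrix
# powers (independent of the union-find in dedup_identical)
oracle_equiv_classes <- function(n, pair_fn) {
  adj <- diag(TRUE, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (pair_fn(i, j)) adj[i, j] <- adj[j, i] <- TRUE
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1L
    comp[which(reach[i, ])] <- cid
  }
  comp
}

# literal greedy sweep per the pruning contract, written independently
oracle_greedy_prune <- function(ids, m, threshold, priority) {
  retained <- character(0); removed <- character(0)
  for (id in ids[priority]) {
    over <- retained[m[id, retained] > threshold]
    if (length(over)) removed[id] <- over[1] else retained <- c(retained, id)
  }
  list(retained = retained, removed = removed)
}

# plain union-find over an edge list
oracle_components <- function(nodes, edges_from, edges_to) {
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(edges_from)) {
    a <- find(edges_from[k]); b <- find(edges_to[k])
    if (a != b) parent[[b]] <- a
  }
  roots <- vapply(nodes, find, "")
  unname(lapply(split(nodes, roots), sort))
}

# exhaustive diagonal scan for internal repeats: for every offset d, slide
# a window of min_len and report maximal windows with identity >= thr
oracle_has_repeat <- function(seq, min_len, thr) {
  v <- strsplit(seq, "")[[1]]
  L <- length(v)
  for (d in min_len:(L - min_len)) {
    eq <- v[1:(L - d)] == v[(1 + d):L]
    if (length(eq) < min_len) next
    cs <- cumsum(eq)
    win <- cs[min_len:length(eq)] - c(0, cs)[1:(length(eq) - min_len + 1L)]
    if (any(win / min_len >= thr / 100)) return(TRUE)
  }
  FALSE
}

skew_closed_form <- function(w, up, dn) {
  v <- strsplit(w, "")[[1]]
  a <- sum(v == up); b <- sum(v == dn)
  if (a + b == 0) 0 else (a - b) / (a + b)
}
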