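# Ground-truthed synthetic inputs. The generator emulates the statistical
# structure of assembly-line PKS cluster DNA: per-module domain blocks
# (KS/AT/ACP plus optional tailoring domains, NRPS C-A-PCP modules in
# hybrids), proteins packed from consecutive modules, intergenic spacers,
# optionally planted GRINS-like skewed duplicated segments, and deposit
# dates drawn from an exponential discovery process. Every output carries
# a truth manifest sufficient to score each pipeline stage.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# fixed back-translation table (one codon per amino acid), chosen for
# near-neutral GC and TA skews so synthetic coding DNA does not mimic
# GRINS-grade compositional bias
CODON_TABLE <- c(A = "GCA", R = "CGT", N = "AAT", D = "GAC", C = "TGC",
                 E = "GAG", Q = "CAG", G = "GGT", H = "CAC", I = "ATC",
                 L = "CTT", K = "AAG", M = "ATG", F = "TTC", P = "CCT",
                 S = "AGT", T = "ACT", V = "GTT", W = "TGG", Y = "TAC")

# frozen synthetic consensus ketosynthase (430 aa). This stands in for a
# real multi-PKS KS consensus; it is a synthetic sequence with a loosely
# KS-like composition, shipped in inst/extdata/synthetic_consensus_ks.faa.
SYNTH_CONSENSUS_KS <- paste0(
  "DHPTTVTVLKFHLTDSGRGQHTRSMLPTALVWNMESIFPESVGVAQHHFDTQVLEGAKSSGEGDNYHSCVVASRSLLWDVDAASTP",
  "EPVTTTAYGTGGCSVGSKPKVGLTDTGLKYGDPFRDVADKGTGRTFLSGIVRIVVLVVCPPSGCMRSGAPKPGHDADAMEKLYAVV",
  "TVGQAPDQLGLADTRPCGGTPAKTNPYEFPVGAQRIFKAFVRVAARAGGASHPMGTSILLLQPPNSNGESGPECIAEFTGYLVIDA",
  "PTEQTHPWVQLFPDYFGANQQIGKGKLFAARTVEPGFKCTAVWDKMHQSAVGTDGEIEGSCDVNVIGYVGEPVDGGASLIELFISC",
  "GTADAWGPPAVKIENIAYSAKLLGKARVYSELRAQDGVNVRVRQVESEASMLEVDMQALNIPFPDIKDADFQHVSPSTSFCDSDAK")

#' The synthetic consensus KS protein
#'
#' A frozen 430-residue synthetic ketosynthase-like sequence. Every KS
#' block emitted by [generate_cluster()] is a diverged copy of it, so
#' [scan_ks()] can recover planted KS domains with this consensus as the
#' query.
#'
#' @return Amino-acid string.
#' @export
synthetic_consensus_ks <- function() SYNTH_CONSENSUS_KS

DOMAIN_AA_LEN <- c(KS = 430L, AT = 330L, ACP = 85L, KR = 450L, DH = 280L,
                   ER = 310L, MT = 100L, TE = 90L, C = 450L, A = 500L,
                   PCP = 80L)

# minimum residues between a module's KS and the next KS (tailoring
# domains, carrier protein and inter-domain linkers). Real cis-AT modules
# run 1500-2000 aa, so consecutive KS domains sit more than 3 kbp apart;
# modules whose sampled domains fall short are padded with linker sequence
# to keep that geometry.
MODULE_TAIL_AA <- 1100L

# mild per-kind composition biases so different domain kinds look
# compositionally distinct without skewing the coding DNA
kind_aa_weights <- function(kind) {
  w <- setNames(rep(1, 20), AA20)
  bump <- switch(kind,
    AT = c(S = 2, H = 1.5, G = 1.5), ACP = c(D = 2, E = 2, S = 1.5),
    KR = c(G = 2, K = 1.5), DH = c(H = 2, P = 1.5), ER = c(V = 1.5, G = 1.5),
    MT = c(M = 2, G = 1.5), TE = c(S = 2, G = 1.5), C = c(H = 2, D = 1.5),
    A = c(T = 1.5, S = 1.5), PCP = c(S = 2, D = 1.5), NULL)
  if (!is.null(bump)) w[names(bump)] <- w[names(bump)] + bump
  w
}

random_aa <- function(len, kind = "other") {
  w <- kind_aa_weights(kind)
  paste(sample(AA20, len, replace = TRUE, prob = w), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_aa_string <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(AA20, v[i]), 1L)
  paste(v, collapse = "")
}

mutate_dna_string <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

#' Back-translate a protein with the package's fixed codon table
#'
#' @param aa Amino-acid string over the 20 standard residues.
#' @return DNA string of length `3 * nchar(aa)`.
#' @export
back_translate <- function(aa) {
  v <- strsplit(toupper(aa), "")[[1]]
  if (!all(v %in% names(CODON_TABLE)))
    stop("back_translate: non-standard residue(s): ",
         paste(setdiff(v, names(CODON_TABLE)), collapse = " "))
  paste(CODON_TABLE[v], collapse = "")
}

#' A GRINS-like skewed DNA segment
#'
#' The default composition gives GC and TA skews of about +0.6 --
#' "intense" skews well clear of the 25% detection threshold, as in real
#' GRINS. (A region whose mean skew sits *at* the threshold is not a
#' reliable ground-truth positive: individual 150 bp windows fluctuate by
#' roughly 0.1 around the regional mean, so per-window thresholding
#' fragments marginal regions.)
#'
#' @param len Segment length in bp (default 1000).
#' @param comp Named nucleotide frequencies.
#' @return DNA string.
#' @export
skewed_segment <- function(len = 1000,
                           comp = c(A = 0.12, C = 0.08, G = 0.32, T = 0.48)) {
  paste(sample(names(comp), len, replace = TRUE, prob = comp), collapse = "")
}

# module grammar for a target pks_type; returns list of character vectors
# (domain kinds per module)
default_module_grammar <- function(n_modules, pks_type) {
  stopifnot(n_modules >= 1L)
  hybrid <- grepl("hybrid", pks_type)
  mode <- if (grepl("^cis", pks_type)) "cis"
          else if (grepl("^trans", pks_type)) "trans"
          else if (grepl("^mixed", pks_type)) "mixed" else "other"
  cis_flags <- switch(mode,
    cis = rep(TRUE, n_modules),
    trans = rep(FALSE, n_modules),
    mixed = {
      if (n_modules < 2L)
        stop("default_module_grammar: mixed type needs >= 2 modules")
      f <- rep(FALSE, n_modules); f[seq_len(ceiling(n_modules / 2))] <- TRUE; f
    },
    other = rep(FALSE, n_modules))
  mods <- lapply(seq_len(n_modules), function(i) {
    m <- "KS"
    if (cis_flags[i]) m <- c(m, "AT")
    if (runif(1) < 0.5) m <- c(m, "KR")
    if (runif(1) < 0.3) m <- c(m, "DH")
    if (mode != "other") m <- c(m, "ACP")
    m
  })
  mods[[n_modules]] <- c(mods[[n_modules]], "TE")
  if (hybrid || mode == "other") {
    nrps <- list(c("C", "A", "PCP"))
    mods <- append(mods, nrps, after = max(1L, n_modules - 1L))
  }
  mods
}

# classify a grammar (list of kind vectors) with the same rules as
# classify_cluster, used for spec-consistency checks
grammar_label <- function(grammar) {
  kinds <- unlist(grammar)
  hybrid <- any(kinds %in% c("C", "A", "PCP"))
  if (!any(kinds == "AT") && !any(kinds == "ACP")) return("other hybrid")
  ks_mods <- which(vapply(grammar, function(m) "KS" %in% m, logical(1)))
  cis <- vapply(ks_mods, function(i) "AT" %in% grammar[[i]], logical(1))
  base <- if (all(cis)) "cis-AT" else if (!any(cis)) "trans-AT"
          else "mixed cis/trans"
  if (base == "mixed cis/trans")
    return(if (hybrid) "mixed cis/trans hybrid" else "mixed cis/trans PKS")
  paste0(base, if (hybrid) " PKS-NRPS hybrid" else " PKS")
}

#' Generate a synthetic assembly-line PKS cluster
#'
#' Emits a nucleotide record containing one cluster: per-module domain
#' blocks back-translated with the fixed codon table, consecutive modules
#' packed into proteins separated by intergenic spacers, flanking
#' background sequence, and (optionally) GRINS-like planted segments --
#' duplicated, strongly skewed 1 kbp blocks placed in two distinct
#' intergenic spacers. Every KS block is a diverged copy of
#' [synthetic_consensus_ks()] so the scanning stage can recover it.
#'
#' @param n_modules Number of PKS modules (KS-containing); clusters with
#'   fewer than `min_ks` modules yield `cluster = NULL` (designed negative
#'   controls).
#' @param pks_type Target type label from [pks_types()].
#' @param seed Integer seed; identical arguments and seed reproduce
#'   identical bytes.
#' @param module_grammar Optional explicit grammar (list of domain-kind
#'   vectors, one per module). Must be consistent with `pks_type`.
#' @param grins_copies 0 (default) or 2: number of planted GRINS copies.
#' @param grins_len Planted segment length (default 1000 bp).
#' @param grins_divergence Substitution rate applied to the second copy
#'   (default 0.01).
#' @param ks_divergence Per-residue divergence of each KS block from the
#'   consensus (default 0.18; keeps distinct KS blocks well below the
#'   internal-repeat identity threshold while trivially recoverable by
#'   alignment).
#' @param modules_per_protein Packing density (default 2).
#' @param spacer_len Mean intergenic spacer length (default 300 bp).
#' @param flank_len Background flank on each side of the cluster
#'   (default 1500 bp).
#' @param cluster_id,species,phylum,deposit_date,known_product Metadata.
#' @param min_ks Minimum KS count for a `pks_cluster` to be built.
#' @return List with `record` ([nt_record()]), `proteins` (named vector),
#'   `domains` ([domain_annotations()]), `locations` (protein placement
#'   data frame), `cluster` ([pks_cluster()] or NULL), and `truth`
#'   (manifest: KS spans, cluster span, GRINS plants, grammar, type
#'   label, layout).
#' @export
generate_cluster <- function(n_modules = 5, pks_type = "cis-AT PKS",
                             seed = 1, module_grammar = NULL,
                             grins_copies = 0, grins_len = 1000,
                             grins_divergence = 0.01, ks_divergence = 0.18,
                             modules_per_protein = 2, spacer_len = 300,
                             flank_len = 1500, cluster_id = "synthC1",
                             species = "Synthetica exemplaris",
                             phylum = "actinobacteria", deposit_date = NA,
                             known_product = FALSE, min_ks = 3L) {
  stopifnot(pks_type %in% PKS_TYPES, grins_copies %in% c(0L, 2L))
  withr::local_seed(seed)
  if (is.null(module_grammar)) {
    module_grammar <- default_module_grammar(n_modules, pks_type)
  } else if (grammar_label(module_grammar) != pks_type) {
    stop("generate_cluster: module_grammar is inconsistent with pks_type '",
         pks_type, "' (grammar implies '",
         grammar_label(module_grammar), "')")
  }
  # build per-module amino-acid blocks with linkers
  linker <- function() random_aa(15L, "other")
  mod_seqs <- lapply(module_grammar, function(kinds) {
    doms <- lapply(kinds, function(kind) {
      if (kind == "KS") mutate_aa_string(SYNTH_CONSENSUS_KS, ks_divergence)
      else random_aa(DOMAIN_AA_LEN[[kind]], kind)
    })
    list(kinds = kinds, doms = doms)
  })
  # pack consecutive modules into proteins
  n_mod <- length(mod_seqs)
  prot_of_module <- ceiling(seq_len(n_mod) / modules_per_protein)
  n_prot <- max(prot_of_module)
  prot_ids <- sprintf("%s_p%02d", cluster_id, seq_len(n_prot))
  proteins <- character(0)
  dom_rows <- list()
  for (p in seq_len(n_prot)) {
    aa <- ""
    for (m in which(prot_of_module == p)) {
      tail_start <- NA_integer_
      for (d in seq_along(mod_seqs[[m]]$kinds)) {
        aa <- paste0(aa, linker())
        st <- nchar(aa)
        aa <- paste0(aa, mod_seqs[[m]]$doms[[d]])
        if (mod_seqs[[m]]$kinds[d] == "KS") tail_start <- nchar(aa)
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          protein_id = prot_ids[p], kind = mod_seqs[[m]]$kinds[d],
          aa_start = st, aa_end = nchar(aa), stringsAsFactors = FALSE)
      }
      if (!is.na(tail_start)) {
        pad <- MODULE_TAIL_AA - (nchar(aa) - tail_start)
        if (pad > 0L) aa <- paste0(aa, random_aa(pad, "other"))
      }
    }
    aa <- paste0(aa, linker())
    proteins[prot_ids[p]] <- aa
  }
  dom_df <- do.call(rbind, dom_rows)
  domains <- domain_annotations(dom_df$protein_id, dom_df$kind,
                                dom_df$aa_start, dom_df$aa_end)
  # choose spacers to carry GRINS plants (interior spacers only)
  plant_spacers <- integer(0)
  plant_seq <- NULL
  if (grins_copies == 2L) {
    if (n_prot < 3L)
      stop("generate_cluster: GRINS plants need >= 3 proteins ",
           "(use modules_per_protein = 1 or more modules)")
    interior <- 2:(n_prot)  # spacer i sits before protein i
    plant_spacers <- sort(sample(interior, 2L))
    plant_seq <- skewed_segment(grins_len)
  }
  # assemble record: flank, then (spacer, CDS) per protein, spacer, flank
  parts <- list(list(type = "flank", seq = random_dna(flank_len)))
  for (p in seq_len(n_prot)) {
    sp <- random_dna(spacer_len)
    if (p %in% plant_spacers) {
      copy <- if (p == plant_spacers[1]) plant_seq
              else mutate_dna_string(plant_seq, grins_divergence)
      sp <- paste0(random_dna(150L), copy, random_dna(150L))
      parts[[length(parts) + 1L]] <- list(type = "spacer_pre", seq = sp,
                                          plant_offset = 150L,
                                          plant_len = nchar(copy))
    } else {
      parts[[length(parts) + 1L]] <- list(type = "spacer_pre", seq = sp)
    }
    parts[[length(parts) + 1L]] <- list(type = "cds", seq = NULL,
                                        protein = prot_ids[p])
  }
  parts[[length(parts) + 1L]] <- list(type = "spacer_pre",
                                      seq = random_dna(spacer_len))
  parts[[length(parts) + 1L]] <- list(type = "flank",
                                      seq = random_dna(flank_len))
  assemble_synth(parts, proteins, domains, cluster_id, species, phylum,
                 deposit_date, known_product, module_grammar, pks_type,
                 min_ks, record_id = paste0(cluster_id, "_rec"))
}

# turn a parts layout + proteins into record/cluster/truth; shared by
# generate_cluster and mutate_homolog so reassembly is deterministic
assemble_synth <- function(parts, proteins, domains, cluster_id, species,
                           phylum, deposit_date, known_product,
                           module_grammar, pks_type, min_ks, record_id) {
  seqs <- character(length(parts))
  for (i in seq_along(parts)) {
    seqs[i] <- if (parts[[i]]$type == "cds")
      back_translate(proteins[[parts[[i]]$protein]])
    else parts[[i]]$seq
  }
  offsets <- cumsum(c(0L, nchar(seqs)))[seq_along(seqs)]
  record_seq <- paste(seqs, collapse = "")
  record <- nt_record(record_id, record_seq, species, phylum, deposit_date)
  # protein locations and per-record KS spans
  loc_rows <- list(); ks_rows <- list(); grins_rows <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (p$type == "cds") {
      pid <- p$protein
      st <- offsets[i]
      loc_rows[[length(loc_rows) + 1L]] <- data.frame(
        protein_id = pid, record_id = record_id, start = st,
        end = st + 3L * nchar(proteins[[pid]]), strand = "+",
        stringsAsFactors = FALSE)
      dd <- domains[domains$protein_id == pid & domains$kind == "KS", ,
                    drop = FALSE]
      for (r in seq_len(nrow(dd))) {
        ks_rows[[length(ks_rows) + 1L]] <- data.frame(
          record_id = record_id, start = st + 3L * dd$aa_start[r],
          end = st + 3L * dd$aa_end[r], stringsAsFactors = FALSE)
      }
    } else if (!is.null(p$plant_offset)) {
      grins_rows[[length(grins_rows) + 1L]] <- data.frame(
        start = offsets[i] + p$plant_offset,
        end = offsets[i] + p$plant_offset + p$plant_len,
        stringsAsFactors = FALSE)
    }
  }
  locations <- do.call(rbind, loc_rows)
  ks_nt <- do.call(rbind, ks_rows)
  ks_nt <- ks_nt[order(ks_nt$start), , drop = FALSE]
  grins_nt <- if (length(grins_rows)) do.call(rbind, grins_rows) else
    data.frame(start = integer(), end = integer())
  cl <- NULL
  span <- c(NA_integer_, NA_integer_)
  if (nrow(ks_nt) >= min_ks) {
    span <- c(ks_nt$start[1], ks_nt$end[nrow(ks_nt)])
    cl <- pks_cluster(
      cluster_id, record_id, span[1], span[2],
      substr(record_seq, span[1] + 1L, span[2]),
      ks_domains(ks_nt$record_id, ks_nt$start, ks_nt$end,
                 rep(1L, nrow(ks_nt))),
      proteins, domains, pks_type = NA_character_, species = species,
      phylum = phylum, deposit_date = deposit_date,
      known_product = known_product, min_ks = min_ks)
  }
  list(record = record, proteins = proteins, domains = domains,
       locations = locations, cluster = cl,
       truth = list(cluster_id = cluster_id, ks_nt = ks_nt,
                    span = span, grins = grins_nt,
                    module_grammar = module_grammar, pks_type = pks_type,
                    layout = parts, min_ks = min_ks))
}

#' Mutate a synthetic cluster into a homolog
#'
#' Substitutions are applied per residue to every protein (each hit
#' residue becomes one of the 19 others) and per site to the non-coding
#' segments (spacers, flanks and GRINS plants); optional indels
#' (insertions/deletions of single residues) are applied to proteins with
#' domain coordinates remapped. The DNA is rebuilt from the mutated parts
#' with the same deterministic assembly as [generate_cluster()], so rate 0
#' reproduces the parent exactly.
#'
#' @param gen Output of [generate_cluster()] (or of this function).
#' @param subst_rate Per-residue substitution probability in `[0, 1)`.
#' @param indel_rate Per-residue indel probability in `[0, 1)`
#'   (default 0).
#' @param seed Integer seed.
#' @param cluster_id,species,deposit_date,known_product Metadata for the
#'   homolog (defaults keep the parent's species).
#' @return Same structure as [generate_cluster()].
#' @export
mutate_homolog <- function(gen, subst_rate, indel_rate = 0, seed = 1,
                           cluster_id = paste0(gen$truth$cluster_id, "_h"),
                           species = gen$record$species,
                           deposit_date = gen$record$deposit_date,
                           known_product = FALSE) {
  stopifnot(subst_rate >= 0, subst_rate < 1, indel_rate >= 0, indel_rate < 1)
  withr::local_seed(seed)
  old_ids <- names(gen$proteins)
  new_ids <- setNames(sprintf("%s_p%02d", cluster_id, seq_along(old_ids)),
                      old_ids)
  proteins <- character(0)
  dom_list <- list()
  for (pid in old_ids) {
    v <- strsplit(gen$proteins[[pid]], "")[[1]]
    hit <- which(runif(length(v)) < subst_rate)
    for (i in hit) v[i] <- sample(setdiff(AA20, v[i]), 1L)
    # indels with coordinate remapping: offset[i] = new position shift of
    # old residue i
    dd <- gen$domains[gen$domains$protein_id == pid, , drop = FALSE]
    if (indel_rate > 0) {
      del <- runif(length(v)) < indel_rate / 2
      ins <- runif(length(v)) < indel_rate / 2
      shift <- cumsum(as.integer(ins) - as.integer(del))
      new_v <- character(0)
      for (i in seq_along(v)) {
        if (ins[i]) new_v <- c(new_v, sample(AA20, 1L))
        if (!del[i]) new_v <- c(new_v, v[i])
      }
      map <- function(pos) {  # old 0-based -> new 0-based
        if (pos == 0L) return(0L)
        max(0L, pos + shift[min(pos, length(shift))])
      }
      dd$aa_start <- vapply(dd$aa_start, map, integer(1))
      dd$aa_end <- pmax(dd$aa_start + 1L,
                        vapply(dd$aa_end, map, integer(1)))
      v <- new_v
    }
    proteins[new_ids[[pid]]] <- paste(v, collapse = "")
    dd$protein_id <- new_ids[[pid]]
    dom_list[[length(dom_list) + 1L]] <- dd
  }
  dom_df <- do.call(rbind, dom_list)
  domains <- domain_annotations(dom_df$protein_id, dom_df$kind,
                                dom_df$aa_start, dom_df$aa_end)
  parts <- lapply(gen$truth$layout, function(p) {
    if (p$type == "cds") p$protein <- new_ids[[p$protein]]
    else p$seq <- mutate_dna_string(p$seq, subst_rate)
    p
  })
  assemble_synth(parts, proteins, domains, cluster_id, species,
                 gen$record$phylum, deposit_date, known_product,
                 gen$truth$module_grammar, gen$truth$pks_type,
                 gen$truth$min_ks, record_id = paste0(cluster_id, "_rec"))
}

# byte-identical copy of a generated cluster under fresh record/protein
# ids (same species): the multiple-accession duplicate that exact
# deduplication must remove
clone_synth <- function(gen, cluster_id, deposit_date) {
  old_ids <- names(gen$proteins)
  new_ids <- setNames(sprintf("%s_p%02d", cluster_id, seq_along(old_ids)),
                      old_ids)
  proteins <- setNames(unname(gen$proteins), new_ids[old_ids])
  domains <- gen$domains
  domains$protein_id <- unname(new_ids[domains$protein_id])
  parts <- lapply(gen$truth$layout, function(p) {
    if (p$type == "cds") p$protein <- new_ids[[p$protein]]
    p
  })
  assemble_synth(parts, proteins, domains, cluster_id,
                 gen$record$species, gen$record$phylum, deposit_date,
                 known_product = FALSE, gen$truth$module_grammar,
                 gen$truth$pks_type, gen$truth$min_ks,
                 record_id = paste0(cluster_id, "_rec"))
}

#' Deposit dates from an exponential discovery process
#'
#' Dates are drawn from the truncated density proportional to
#' `exp(rate * t)` over `[date_range[1], date_range[2] + 1)` (calendar
#' years) by inverse-CDF sampling.
#'
#' @param n Number of dates.
#' @param growth_rate Per-year exponential rate (default `log(2)/2.5`,
#'   i.e. a 2.5-year doubling time).
#' @param date_range Two integer years (default `c(1994, 2022)`).
#' @param seed Integer seed.
#' @return Vector of `Date`s.
#' @export
generate_deposit_dates <- function(n, growth_rate = log(2) / 2.5,
                                   date_range = c(1994L, 2022L), seed = 1) {
  withr::local_seed(seed)
  y0 <- date_range[1]; y1 <- date_range[2] + 1L
  u <- runif(n)
  t <- log(u * (exp(growth_rate * (y1 - y0)) - 1) + 1) / growth_rate + y0
  yr <- pmin(floor(t), date_range[2])
  frac <- t - floor(t)
  as.Date(paste0(yr, "-01-01")) + floor(frac * 365)
}

#' Generate a ground-truthed synthetic catalogue
#'
#' `n_families` unrelated base clusters, each expanded into `family_size`
#' homologs at the given amino-acid divergence (members carry distinct
#' species so exact deduplication does not collapse them; redundancy
#' removal at the 90% threshold should). Optionally adds exact duplicate
#' clusters (same species, same sequence) that exact deduplication must
#' remove. Deposit dates follow [generate_deposit_dates()]. Clusters are
#' classified on construction.
#'
#' @param n_families Number of distinct assembly lines.
#' @param family_size Homologs per family (1 = no redundancy).
#' @param divergence Within-family amino-acid divergence (default 0.02;
#'   pairwise similarity ~96-98%, comfortably above the 90% redundancy
#'   threshold).
#' @param growth_rate,date_range,seed See [generate_deposit_dates()].
#' @param n_exact_duplicates Extra same-species exact copies (default 0).
#' @param known_families Fraction of families whose representative is
#'   flagged as a known producer (default 0.2).
#' @param n_modules_range Range of module counts sampled per family
#'   (default 3:5).
#' @param modules_per_protein Passed to [generate_cluster()].
#' @return List with `clusters` (list of classified [pks_cluster()]s),
#'   `generated` (the full generator outputs, by cluster id) and `truth`
#'   (family id, redundant ids, duplicate ids, known ids, dates).
#' @export
generate_catalog <- function(n_families = 8, family_size = 2,
                             divergence = 0.02,
                             growth_rate = log(2) / 2.5,
                             date_range = c(1994L, 2022L), seed = 1,
                             n_exact_duplicates = 0, known_families = 0.2,
                             n_modules_range = 3:5,
                             modules_per_protein = 2) {
  withr::local_seed(seed)
  type_pool <- c("cis-AT PKS", "cis-AT PKS-NRPS hybrid", "trans-AT PKS",
                 "trans-AT PKS-NRPS hybrid", "mixed cis/trans PKS",
                 "mixed cis/trans hybrid", "other hybrid")
  type_w <- c(0.36, 0.28, 0.07, 0.10, 0.05, 0.05, 0.09)
  phyla <- c("actinobacteria", "proteobacteria", "cyanobacteria",
             "firmicutes", "bacteroidetes", "amoebozoa")
  phyla_w <- c(0.45, 0.2, 0.12, 0.1, 0.06, 0.07)
  fam_types <- sample(type_pool, n_families, replace = TRUE, prob = type_w)
  fam_phyla <- sample(phyla, n_families, replace = TRUE, prob = phyla_w)
  fam_mods <- sample(n_modules_range, n_families, replace = TRUE)
  fam_seeds <- sample.int(2^20, n_families + 1L)
  known_fam <- sample(n_families, round(known_families * n_families))
  n_total <- n_families * family_size + n_exact_duplicates
  dates <- sort(generate_deposit_dates(n_total, growth_rate, date_range,
                                       seed = fam_seeds[n_families + 1L]))
  dates <- sample(dates)  # random assignment to clusters
  gens <- list(); family <- character(0); known_ids <- character(0)
  di <- 0L
  for (f in seq_len(n_families)) {
    # mixed types need >= 2 modules; NRPS module is added on top of KS ones
    nm <- max(fam_mods[f], if (grepl("mixed", fam_types[f])) 4L else 3L)
    base_id <- sprintf("F%02dM01", f)
    di <- di + 1L
    base <- generate_cluster(
      n_modules = nm, pks_type = fam_types[f], seed = fam_seeds[f],
      cluster_id = base_id,
      species = sprintf("Synthetica familia%02da", f),
      phylum = fam_phyla[f], deposit_date = dates[di],
      known_product = f %in% known_fam,
      modules_per_protein = modules_per_protein)
    gens[[base_id]] <- base
    family[base_id] <- sprintf("F%02d", f)
    if (f %in% known_fam) known_ids <- c(known_ids, base_id)
    if (family_size > 1L) for (m in 2:family_size) {
      id <- sprintf("F%02dM%02d", f, m)
      di <- di + 1L
      gens[[id]] <- mutate_homolog(
        base, subst_rate = divergence, seed = fam_seeds[f] + 7919L * m,
        cluster_id = id,
        species = sprintf("Synthetica familia%02d%s", f, letters[m]),
        deposit_date = dates[di])
      family[id] <- sprintf("F%02d", f)
    }
  }
  dup_ids <- character(0)
  if (n_exact_duplicates > 0) {
    srcs <- sample(names(gens), n_exact_duplicates, replace = TRUE)
    for (d in seq_len(n_exact_duplicates)) {
      id <- sprintf("DUP%02d", d)
      di <- di + 1L
      gens[[id]] <- clone_synth(gens[[srcs[d]]], id, dates[di])
      dup_ids <- c(dup_ids, id)
      family[id] <- family[srcs[d]]
    }
  }
  clusters <- lapply(gens, function(g) {
    cl <- g$cluster
    cl$pks_type <- classify_cluster(cl)
    cl
  })
  redundant <- names(family)[duplicated(family)]
  list(clusters = clusters, generated = gens,
       truth = list(family = family, redundant_ids = redundant,
                    duplicate_ids = dup_ids, known_ids = known_ids,
                    n_families = n_families,
                    dates = setNames(dates[seq_along(family)],
                                     names(family))))
}
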