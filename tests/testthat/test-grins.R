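# Nucleotide skews, skewed-region calling, internal repeats, GRINS.

revcomp_str <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("skews match their closed forms and flag degenerate windows", {
  expect_equal(as.numeric(gc_skew("GGGGCC")), 1 / 3, tolerance = 1e-12)
  expect_equal(as.numeric(ta_skew("TTTA")), 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(gc_skew("ATATAT")), 0)
  expect_true(attr(gc_skew("ATATAT"), "degenerate"))
  expect_equal(as.numeric(ta_skew("GCGC")), 0)
  expect_true(attr(ta_skew("GCGC"), "degenerate"))
  expect_error(gc_skew(""), "empty")
  # exhaustive 4-mers against the closed form
  mers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1,
                paste, collapse = "")
  for (w in mers) {
    expect_equal(as.numeric(gc_skew(w)), skew_closed_form(w, "G", "C"))
    expect_equal(as.numeric(ta_skew(w)), skew_closed_form(w, "T", "A"))
  }
})

test_that("reverse complement negates both skews", {
  set.seed(31)
  for (i in 1:300) {
    w <- random_dna_str(sample(10:200, 1))
    expect_equal(as.numeric(gc_skew(revcomp_str(w))),
                 -as.numeric(gc_skew(w)), tolerance = 1e-12)
    expect_equal(as.numeric(ta_skew(revcomp_str(w))),
                 -as.numeric(ta_skew(w)), tolerance = 1e-12)
  }
})

test_that("skew profiles tile the sequence as specified", {
  set.seed(32)
  s <- random_dna_str(300)
  prof <- skew_profile(s, 150, 30)
  expect_equal(nrow(prof), 6L)   # floor((300-150)/30)+1
  expect_equal(prof$start, seq(0L, 150L, by = 30L))
  # homogeneous sequence: constant profile
  hom <- skew_profile(strrep("ACGT", 200), 100, 20)
  expect_true(all(hom$gc_skew == hom$gc_skew[1]))
  expect_true(all(hom$ta_skew == hom$ta_skew[1]))
  # windowed locality: away from the seam, the profile of a concatenation
  # equals the concatenated profiles
  a <- random_dna_str(600); b <- random_dna_str(600)
  pa <- skew_profile(a, 150, 30); pab <- skew_profile(paste0(a, b), 150, 30)
  inside <- pa$start + 150 <= 600
  expect_equal(pab$gc_skew[seq_len(sum(inside))], pa$gc_skew[inside])
  expect_warning(p0 <- skew_profile("ACGT", 150, 30), "shorter")
  expect_equal(nrow(p0), 0L)
})

test_that("profile values agree with per-window skew calls", {
  set.seed(33)
  s <- random_dna_str(1000)
  prof <- skew_profile(s, 150, 50)
  for (k in seq_len(nrow(prof))) {
    w <- substr(s, prof$start[k] + 1, prof$start[k] + 150)
    expect_equal(prof$gc_skew[k], as.numeric(gc_skew(w)), tolerance = 1e-12)
    expect_equal(prof$ta_skew[k], as.numeric(ta_skew(w)), tolerance = 1e-12)
  }
})

test_that("skewed regions are recovered where planted and need both skews", {
  set.seed(34)
  plant <- skewed_segment(1000)
  s <- paste0(random_dna_str(3000), plant, random_dna_str(3000))
  reg <- find_skewed_regions(skew_profile(s, 150, 30), 0.25, 700)
  expect_equal(nrow(reg), 1L)
  expect_lte(abs(reg$start - 3000), 150)
  expect_lte(abs(reg$end - 4000), 150)
  expect_gt(reg$mean_gc_skew, 0.25)
  expect_gt(reg$mean_ta_skew, 0.25)

  # GC-only skew is not reported (conjunctive rule)
  gc_only <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE,
                          prob = c(0.25, 0.08, 0.42, 0.25)), collapse = "")
  s2 <- paste0(random_dna_str(2000), gc_only, random_dna_str(2000))
  expect_equal(nrow(find_skewed_regions(skew_profile(s2, 150, 30),
                                        0.25, 700)), 0L)
})

test_that("neutral sequence rarely yields a false skewed region", {
  false_hits <- 0L
  for (i in 1:100) {
    set.seed(5000 + i)
    s <- random_dna_str(8000)
    reg <- find_skewed_regions(skew_profile(s, 150, 30), 0.25, 700)
    false_hits <- false_hits + (nrow(reg) > 0L)
  }
  expect_lte(false_hits, 2L)
})

test_that("internal repeats: exact and mutated duplications recovered,
           shuffled controls clean", {
  set.seed(35)
  unit <- random_dna_str(1000)
  s <- paste0(random_dna_str(2000), unit, random_dna_str(11000), unit,
              random_dna_str(2000))
  reps <- find_internal_repeats(s, 90, 700)
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$identity, 100)
  expect_lte(abs(reps$start1 - 2000), 20)
  expect_lte(abs(reps$end1 - 3000), 20)
  expect_lte(abs(reps$start2 - 14000), 20)
  expect_lte(abs(reps$end2 - 15000), 20)

  # 5% per-site mutated copy: identity in the binomial band
  v <- strsplit(unit, "")[[1]]
  hit <- which(runif(1000) < 0.05)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  s5 <- paste0(random_dna_str(2000), unit, random_dna_str(9000),
               paste(v, collapse = ""), random_dna_str(2000))
  r5 <- find_internal_repeats(s5, 90, 700)
  expect_equal(nrow(r5), 1L)
  expect_gte(r5$identity, 93)
  expect_lte(r5$identity, 97)

  shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(nrow(find_internal_repeats(shuf, 90, 700)), 0L)
})

test_that("repeat detection decisions match the diagonal-scan oracle", {
  for (trial in 1:120) {
    set.seed(6000 + trial)
    kind <- trial %% 3
    if (kind == 0) {            # no repeat
      s <- random_dna_str(2600)
    } else if (kind == 1) {     # exact 800 bp duplication
      u <- random_dna_str(800)
      s <- paste0(random_dna_str(300), u, random_dna_str(400), u,
                  random_dna_str(300))
    } else {                    # strongly mutated copy (below threshold)
      u <- random_dna_str(800)
      v <- strsplit(u, "")[[1]]
      hit <- which(runif(800) < 0.25)
      for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
      s <- paste0(random_dna_str(300), u, random_dna_str(400),
                  paste(v, collapse = ""), random_dna_str(300))
    }
    got <- nrow(find_internal_repeats(s, 90, 700)) > 0L
    want <- oracle_has_repeat(s, 700, 90)
    expect_identical(got, want)
  }
})

test_that("GRINS requires both the repeat and the skew (worked cases)", {
  g <- generate_cluster(n_modules = 5, seed = 36, modules_per_protein = 1,
                        grins_copies = 2)
  det <- detect_grins(g$cluster)
  expect_equal(nrow(det), 2L)
  truth_rel <- g$truth$grins
  truth_rel$start <- truth_rel$start - g$truth$span[1]
  truth_rel$end <- truth_rel$end - g$truth$span[1]
  for (k in 1:2) {
    hit <- which(abs(det$start - truth_rel$start[k]) <= 150)
    expect_length(hit, 1L)
    expect_lte(abs(det$end[hit] - truth_rel$end[k]), 150)
    expect_gte(det$repeat_identity[hit], 90)
  }
  # partners point at each other
  expect_lte(abs(det$partner_start[1] - det$start[2]), 160)
  expect_lte(abs(det$partner_start[2] - det$start[1]), 160)

  # skewed but unique segment: no GRINS
  set.seed(37)
  uniq <- stub_cluster("u", sequence = paste0(
    random_dna_str(3000), skewed_segment(1000), random_dna_str(3000)))
  expect_equal(nrow(detect_grins(uniq)), 0L)

  # duplicated but unskewed segment: no GRINS
  unit <- random_dna_str(1000)
  dup <- stub_cluster("d", sequence = paste0(
    random_dna_str(2000), unit, random_dna_str(3000), unit,
    random_dna_str(2000)))
  expect_equal(nrow(detect_grins(dup)), 0L)
})

test_that("detections shift exactly with a planted flank", {
  set.seed(38)
  # an exact duplication of a skewed unit so repeat and skew line up
  unit <- skewed_segment(1000)
  core <- paste0(random_dna_str(2400), unit, random_dna_str(4000), unit,
                 random_dna_str(2400))
  d1 <- detect_grins(stub_cluster("x", sequence = core))
  flank <- 300L  # a multiple of the window step
  d2 <- detect_grins(stub_cluster("x", sequence = paste0(
    random_dna_str(flank), core)))
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d2$start, d1$start + flank)
  expect_equal(d2$end, d1$end + flank)
})

test_that("GRINS prevalence tabulates per group", {
  cls <- list(
    stub_cluster("g1", pks_type = "cis-AT PKS", phylum = "actinobacteria"),
    stub_cluster("g2", pks_type = "cis-AT PKS", phylum = "actinobacteria"),
    stub_cluster("g3", pks_type = "cis-AT PKS", phylum = "firmicutes"),
    stub_cluster("g4", pks_type = "cis-AT PKS", phylum = NA),
    stub_cluster("g5", pks_type = "trans-AT PKS", phylum = "firmicutes"))
  cat0 <- pks_catalog(cls)
  fake_det <- function(n)
    data.frame(cluster_id = "x", start = 0L, end = 1000L,
               mean_gc_skew = 0.4, mean_ta_skew = 0.4,
               partner_start = 2000L, partner_end = 3000L,
               repeat_identity = 95)[rep(1, length.out = n), , drop = FALSE]
  det <- list(g1 = fake_det(1), g2 = fake_det(0), g3 = fake_det(0),
              g4 = fake_det(2), g5 = fake_det(0))
  by_type <- grins_prevalence(cat0, det, "pks_type")
  cis <- by_type[by_type$group == "cis-AT PKS", ]
  expect_equal(cis$n_clusters, 4L)
  expect_equal(cis$n_with_grins, 2L)
  expect_equal(cis$percent, 50)
  expect_false("other hybrid" %in% by_type$group)  # empty groups absent
  expect_equal(by_type$percent,
               100 * by_type$n_with_grins / by_type$n_clusters)
  by_ph <- grins_prevalence(cat0, det, "phylum")
  expect_true("unclassified" %in% by_ph$group)
  expect_error(grins_prevalence(cat0, det[1:3], "pks_type"), "missing")
  expect_error(grins_prevalence(cat0, det, "species"), "arg")
})
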