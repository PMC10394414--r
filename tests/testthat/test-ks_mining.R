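# KS scanning, hit discretization, cluster calling, classification.

test_that("scan_ks recovers a planted consensus copy on either strand", {
  set.seed(11)
  ks_dna <- back_translate(synthetic_consensus_ks())
  rec <- nt_record("r1", paste0(random_dna_str(2000), ks_dna,
                                random_dna_str(2000)))
  hits <- scan_ks(rec, synthetic_consensus_ks())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_lte(abs(hits$start - 2000), 15)       # within 5 codons
  expect_lte(abs(hits$end - (2000 + nchar(ks_dna))), 15)
  expect_gt(hits$percent_identity, 99)

  # same copy on the minus strand
  rc <- nt_record("r2", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rec$sequence))))
  hits_rc <- scan_ks(rc, synthetic_consensus_ks())
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
  expect_lte(abs(hits_rc$start - 2000), 15)
  expect_lte(abs(hits_rc$end - (2000 + nchar(ks_dna))), 15)
})

test_that("scan_ks is silent on random sequence and rejects bad input", {
  set.seed(12)
  rec <- nt_record("r", random_dna_str(10000))
  expect_equal(nrow(scan_ks(rec, synthetic_consensus_ks())), 0L)
  expect_error(scan_ks(rec, ""), "empty consensus")
  expect_error(scan_ks(nt_record("s", "AC"), synthetic_consensus_ks()),
               "shorter")
})

test_that("scan_ks finds every planted KS of a synthetic cluster", {
  g <- generate_cluster(n_modules = 4, seed = 33)
  hits <- scan_ks(g$record, synthetic_consensus_ks())
  expect_equal(nrow(hits), nrow(g$truth$ks_nt))
  expect_true(all(abs(hits$start - g$truth$ks_nt$start) <= 15))
  expect_true(all(abs(hits$end - g$truth$ks_nt$end) <= 15))
})

test_that("discretize_hits merges by gap threshold (worked example)", {
  hits <- ks_hits(rep("r", 3), c(100L, 1600L, 6000L),
                  c(1400L, 2900L, 7300L), rep("+", 3), 0L,
                  rep(90, 3), rep(500, 3))
  doms <- discretize_hits(hits, 3000)
  expect_equal(doms$start, c(100L, 6000L))
  expect_equal(doms$end, c(2900L, 7300L))
  expect_equal(doms$n_source_hits, c(2L, 1L))

  expect_equal(nrow(discretize_hits(ks_hits(), 3000)), 0L)
  one <- discretize_hits(hits[1, ], 3000)
  expect_equal(one$n_source_hits, 1L)
  expect_error(discretize_hits(ks_hits(c("a", "b"), c(0L, 0L),
                                       c(10L, 10L), c("+", "+"), 0L,
                                       c(90, 90), c(1, 1)), 3000),
               "multiple records")
})

test_that("a gap of exactly min_separation merges; just above splits", {
  mk <- function(gap) ks_hits(rep("r", 2), c(0L, 1000L + gap),
                              c(1000L, 2000L + gap), rep("+", 2), 0L,
                              rep(90, 2), rep(1, 2))
  expect_equal(nrow(discretize_hits(mk(3000L), 3000)), 1L)
  expect_equal(nrow(discretize_hits(mk(3001L), 3000)), 2L)
})

test_that("discretize_hits matches the exhaustive merge oracle and is
           idempotent", {
  for (trial in 1:400) {
    set.seed(trial)
    n <- sample(1:40, 1)
    st <- sort(sample(0:60000, n))
    en <- st + sample(200:2000, n, replace = TRUE)
    min_sep <- sample(c(500, 3000, 8000), 1)
    hits <- ks_hits(rep("r", n), st, en, rep("+", n), 0L,
                    rep(90, n), rep(1, n))
    got <- discretize_hits(hits, min_sep)
    want <- oracle_merge_hits(st, en, min_sep)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_source_hits, want$n)
    # output gaps all exceed min_sep; re-application changes nothing
    if (nrow(got) > 1L)
      expect_true(all(got$start[-1] - got$end[-nrow(got)] > min_sep))
    again <- discretize_hits(
      ks_hits(got$record_id, got$start, got$end, rep("+", nrow(got)), 0L,
              rep(90, nrow(got)), rep(1, nrow(got))), min_sep)
    expect_equal(again$start, got$start)
    expect_equal(again$end, got$end)
  }
})

test_that("call_candidate_clusters chains domains (worked example)", {
  doms <- ks_domains(rep("r", 5), c(0L, 5000L, 12000L, 40000L, 45000L),
                     c(0L, 5000L, 12000L, 40000L, 45000L) + 1300L,
                     rep(1L, 5))
  cc <- call_candidate_clusters(doms, 20000, 3)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$start, 0L)
  expect_equal(cc$end, 13300L)
  expect_equal(cc$n_ks, 3L)

  expect_equal(nrow(call_candidate_clusters(doms[1:2, ], 20000, 3)), 0L)

  # both gaps exactly max_gap: boundary is inclusive
  d3 <- ks_domains(rep("r", 3), c(0L, 21300L, 42600L),
                   c(1300L, 22600L, 43900L), rep(1L, 3))
  cc3 <- call_candidate_clusters(d3, 20000, 3)
  expect_equal(nrow(cc3), 1L)
  expect_equal(cc3$n_ks, 3L)
})

test_that("call_candidate_clusters matches the chain-enumeration oracle", {
  for (trial in 1:400) {
    set.seed(1000 + trial)
    n <- sample(0:30, 1)
    st <- sort(sample(0:200000, max(n, 1)))[seq_len(n)]
    en <- st + 1300L
    max_gap <- sample(c(5000, 20000), 1)
    min_ks <- sample(2:4, 1)
    doms <- ks_domains(rep("r", n), st, en, rep(1L, max(n, 0L)))
    got <- call_candidate_clusters(doms, max_gap, min_ks)
    want <- oracle_call_clusters(st, en, max_gap, min_ks)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_ks, want$n_ks)
      expect_true(all(got$n_ks >= min_ks))
    }
  }
})

test_that("classification covers the seven-type scheme", {
  cis <- arch_cluster("c1", list(c("KS", "AT", "ACP"),
                                 c("KS", "AT", "KR", "ACP", "TE")))
  expect_identical(classify_cluster(cis), "cis-AT PKS")

  trans_hyb <- arch_cluster("c2", list(c("KS", "ACP", "KS", "ACP"),
                                       c("C", "A", "PCP"),
                                       c("KS", "ACP", "TE")))
  expect_identical(classify_cluster(trans_hyb), "trans-AT PKS-NRPS hybrid")

  mixed <- arch_cluster("c3", list(c("KS", "AT", "ACP", "KS", "AT", "ACP"),
                                   c("KS", "ACP", "KS", "ACP", "TE")))
  expect_identical(classify_cluster(mixed), "mixed cis/trans PKS")

  cis_hyb <- arch_cluster("c4", list(c("KS", "AT", "ACP"),
                                     c("C", "A", "PCP"),
                                     c("KS", "AT", "ACP", "TE")))
  expect_identical(classify_cluster(cis_hyb), "cis-AT PKS-NRPS hybrid")

  mixed_hyb <- arch_cluster("c5", list(c("KS", "AT", "ACP", "KS", "ACP"),
                                       c("A", "PCP", "TE")))
  expect_identical(classify_cluster(mixed_hyb), "mixed cis/trans hybrid")

  trans <- arch_cluster("c6", list(c("KS", "ACP", "KS", "ACP", "KS",
                                     "ACP", "TE")))
  expect_identical(classify_cluster(trans), "trans-AT PKS")

  # untypeable KS modules: no AT anywhere, no ACP anywhere
  other <- arch_cluster("c7", list(c("KS", "KR", "KS", "KR"),
                                   c("C", "A", "PCP")))
  expect_identical(classify_cluster(other), "other hybrid")

  no_ks <- arch_cluster("c8", list(c("C", "A", "PCP")))
  expect_error(classify_cluster(no_ks), "no KS")
})

test_that("classification agrees with the generator's target label", {
  for (ty in pks_types()) {
    g <- generate_cluster(n_modules = 4, pks_type = ty, seed = 77)
    expect_identical(classify_cluster(g$cluster), ty)
  }
})
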