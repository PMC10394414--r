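# Pairwise similarity contract, redundancy pruning, rediscovery/novelty.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_prot <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

mut_prot <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(AA, v[i]), 1L)
  paste(v, collapse = "")
}

prot_cluster <- function(id, proteins, species = "Genus species",
                         deposit_date = NA) {
  stub_cluster(id, proteins = proteins, species = species,
               deposit_date = deposit_date)
}

test_that("similarity is 100 on self, symmetric-by-construction, bounded
           and order-invariant", {
  set.seed(21)
  a <- prot_cluster("a", c(p1 = rand_prot(300), p2 = rand_prot(250)))
  b <- prot_cluster("b", c(q1 = mut_prot(a$proteins[[1]], 0.1),
                           q2 = mut_prot(a$proteins[[2]], 0.1)))
  expect_equal(pairwise_similarity(a, a), 100)
  s1 <- pairwise_similarity(a, b)
  s2 <- pairwise_similarity(b, a)
  expect_equal(s1, s2)
  expect_gte(s1, 0); expect_lte(s1, 100)
  # permuting protein order changes nothing
  b_perm <- b
  b_perm$proteins <- b$proteins[c(2, 1)]
  expect_equal(pairwise_similarity(a, b_perm), s1)
  expect_error(pairwise_similarity(a, prot_cluster("e", character(0))),
               "without proteins")
})

test_that("close homologs score high, unrelated random proteins score low", {
  set.seed(22)
  a <- prot_cluster("a", c(p1 = rand_prot(400), p2 = rand_prot(350)))
  hom <- prot_cluster("h", vapply(a$proteins, mut_prot, "", rate = 0.05))
  expect_gte(pairwise_similarity(a, hom), 90)
  unrel <- prot_cluster("u", c(r1 = rand_prot(400), r2 = rand_prot(350)))
  expect_lt(pairwise_similarity(a, unrel), 15)
})

test_that("scores decrease monotonically along a divergence series", {
  set.seed(23)
  a <- prot_cluster("a", c(p1 = rand_prot(350), p2 = rand_prot(300)))
  rates <- seq(0, 0.5, by = 0.1)
  scores <- vapply(seq_along(rates), function(k) {
    set.seed(500 + k)
    h <- prot_cluster("h", vapply(a$proteins, mut_prot, "",
                                  rate = rates[k]))
    pairwise_similarity(a, h)
  }, numeric(1))
  expect_equal(scores[1], 100)
  expect_true(all(diff(scores) <= 0))
})

test_that("similarity_matrix is symmetric with unit diagonal", {
  set.seed(24)
  base <- rand_prot(250)
  cls <- lapply(1:3, function(i)
    prot_cluster(paste0("m", i), c(p = mut_prot(base, 0.1 * i))))
  m <- similarity_matrix(cls)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(diag(m), setNames(rep(100, 3), paste0("m", 1:3)))
  expect_equal(m, t(m))
  # permuting the input permutes rows/columns consistently
  m2 <- similarity_matrix(cls[c(3, 1, 2)])
  expect_equal(m2[rownames(m), colnames(m)], m)
  one <- similarity_matrix(cls[1])
  expect_equal(unname(one), matrix(100))
})

test_that("greedy pruning follows priority order and records cover
           (worked examples)", {
  mk_matrix <- function(ab, ac, bc) {
    m <- matrix(c(100, ab, ac, ab, 100, bc, ac, bc, 100), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    m
  }
  cls <- list(
    stub_cluster("A", proteins = c(p = strrep("M", 30)),
                 deposit_date = "2000-01-01"),
    stub_cluster("B", proteins = c(p = strrep("M", 30)),
                 deposit_date = "2001-01-01"),
    stub_cluster("C", proteins = c(p = strrep("M", 30)),
                 deposit_date = "2002-01-01"))
  cat1 <- remove_redundant(cls, mk_matrix(95, 40, 42), 90)
  expect_identical(names(cat1$clusters), c("A", "C"))
  expect_identical(cat1$removed, c(B = "A"))

  # chain: A~B, B~C, but A and C dissimilar -> B removed, C kept
  cat2 <- remove_redundant(cls, mk_matrix(95, 60, 95), 90)
  expect_identical(names(cat2$clusters), c("A", "C"))
  expect_identical(cat2$removed, c(B = "A"))

  cat3 <- remove_redundant(cls, mk_matrix(10, 20, 30), 90)
  expect_length(cat3$removed, 0L)
  expect_error(remove_redundant(cls, mk_matrix(10, 20, 30), 101),
               "threshold")
})

test_that("pruning satisfies the retained-max and cover properties on
           random catalogues, matching the greedy oracle", {
  for (trial in 1:200) {
    set.seed(3000 + trial)
    n <- sample(3:20, 1)
    ids <- sprintf("R%02d", seq_len(n))
    m <- matrix(runif(n * n, 0, 100), n, n, dimnames = list(ids, ids))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 100
    dates <- as.Date("1995-01-01") + sample(0:9000, n)
    lens <- sample(1000:9000, n)
    cls <- lapply(seq_len(n), function(i)
      stub_cluster(ids[i], proteins = c(p = strrep("M", lens[i])),
                   deposit_date = dates[i]))
    threshold <- sample(c(50, 90), 1)
    cat0 <- remove_redundant(cls, m, threshold)
    kept <- names(cat0$clusters)
    off <- m[kept, kept, drop = FALSE]
    diag(off) <- 0
    expect_lte(max(off), threshold)
    for (rm in names(cat0$removed))
      expect_gt(m[rm, cat0$removed[[rm]]], threshold)
    want <- oracle_greedy_prune(ids, m, threshold, order(dates, -lens, ids))
    expect_setequal(kept, want$retained)
    expect_identical(cat0$removed[sort(names(cat0$removed))],
                     want$removed[sort(names(want$removed))])
  }
})

test_that("rediscovery series counts later near-copies (worked example)", {
  ids <- c("W", "X", "Y", "Z")
  m <- matrix(5, 4, 4, dimnames = list(ids, ids))
  diag(m) <- 100
  m["W", "Y"] <- m["Y", "W"] <- 97   # third deposit is a near-copy of first
  cls <- lapply(seq_along(ids), function(i)
    stub_cluster(ids[i], deposit_date = sprintf("%d-06-01", 1999 + i)))
  rr <- rediscovery_rate(cls, m, 90)
  expect_equal(rr$year, 2000:2003)
  expect_equal(rr$cumulative_percent, c(0, 0, 100 / 3, 25),
               tolerance = 1e-12)

  m2 <- matrix(5, 4, 4, dimnames = list(ids, ids)); diag(m2) <- 100
  expect_equal(rediscovery_rate(cls, m2, 90)$cumulative_percent,
               rep(0, 4))
  undated <- cls
  undated[[2]]$deposit_date <- as.Date(NA)
  expect_error(rediscovery_rate(undated, m, 90), "X")
})

test_that("nearest characterized neighbour takes the argmax with
           lexicographic ties", {
  ids <- c("o1", "k1", "k2")
  m <- matrix(c(100, 30, 60, 30, 100, 10, 60, 10, 100), 3, 3,
              dimnames = list(ids, ids))
  nn <- nearest_characterized("o1", c("k1", "k2"), m)
  expect_identical(nn$known_id, "k2")
  expect_equal(nn$score, 60)

  m["o1", "k1"] <- m["k1", "o1"] <- 60  # tie -> smaller id
  nn2 <- nearest_characterized("o1", c("k2", "k1"), m)
  expect_identical(nn2$known_id, "k1")
  expect_error(nearest_characterized("o1", character(0), m),
               "no characterized")
})

test_that("novelty fraction uses a strict threshold", {
  nn <- data.frame(orphan_id = c("a", "b", "c"),
                   known_id = "k", score = c(30, 60, 45))
  expect_equal(novelty_fraction(nn, 50), 200 / 3, tolerance = 1e-12)
  expect_equal(novelty_fraction(transform(nn, score = c(50, 60, 70)), 50),
               0)  # exactly 50 is NOT novel
  expect_error(novelty_fraction(nn[0, ]), "empty")
})
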