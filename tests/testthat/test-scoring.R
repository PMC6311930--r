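test_that("score components match hand-computed set arithmetic", {
  expect_equal(inter_g(c("g1", "g2"), c("g1", "g2")), 1)
  expect_equal(inter_g(c("g1", "g2"), c("g2", "g3")), 1 / 3)
  expect_equal(inter_g(character(), character()), 0)

  expect_equal(inter_d("d1", "d1", 10), 1 * 0.1)
  expect_equal(inter_d(c("d1", "d2"), c("d3", "d4"), 10), 0)
  vd <- paste0("d", 1:6)
  expect_equal(inter_d(vd, vd, 6), 1)
  expect_error(inter_d("d1", "d1", 0), "configuration error")

  expect_equal(inter_gd(c("g1", "g2"), c("g1", "g2"),
                        list(c("g1", "g5"))), 1 / 2)
  expect_equal(inter_gd(c("g1"), c("g1"), list()), 0)
  expect_equal(inter_gd(character(), "g1", list("g1")), 0)
  expect_equal(inter_gd(c("g1", "g2"), c("g2", "g1"),
                        list("g1", c("g2", "g9"))), 1)
})

test_that("pair score sums components and respects symmetry", {
  net <- rdg_network(
    drug_gene = data.frame(left_id = c("R1", "R1", "R2", "R2"),
                           right_id = c("g1", "g2", "g2", "g3")),
    drug_disease = data.frame(left_id = c("R1", "R2", "R3"),
                              right_id = c("d1", "d1", "d2")),
    disease_gene = data.frame(left_id = c("d1", "d1"),
                              right_id = c("g2", "g9")))
  s <- inter_score(net, "R2", "R1")
  expect_equal(s$drug_a, "R1")
  expect_equal(s$inter_g, 1 / 3)
  expect_equal(s$inter_d, (1 / 1) * (1 / 2))
  expect_equal(s$inter_gd, 1)   # shared gene g2 is a d1 gene
  expect_equal(s$inter_score, s$inter_g + s$inter_d + s$inter_gd)
  expect_error(inter_score(net, "R1", "ZZ"), "unknown drug")
  # fully disjoint pair scores zero
  expect_equal(inter_score(net, "R1", "R3")$inter_score, 0)
})

test_that("vectorized scoring matches the brute-force oracle", {
  for (seed in 1:20) {
    net <- random_network(seed)
    ranked <- rank_pairs(net)
    for (i in sample(nrow(ranked), min(10, nrow(ranked)))) {
      o <- oracle_score(net, ranked$drug_a[i], ranked$drug_b[i])
      expect_equal(ranked$inter_g[i], o[["inter_g"]], tolerance = 1e-12)
      expect_equal(ranked$inter_d[i], o[["inter_d"]], tolerance = 1e-12)
      expect_equal(ranked$inter_gd[i], o[["inter_gd"]], tolerance = 1e-12)
      expect_equal(ranked$inter_score[i], o[["inter_score"]],
                   tolerance = 1e-12)
    }
    expect_true(all(ranked$inter_g >= 0 & ranked$inter_g <= 1))
    expect_true(all(ranked$inter_d >= 0 & ranked$inter_d <= 1))
    expect_true(all(ranked$inter_gd >= 0 & ranked$inter_gd <= 1))
    expect_true(all(ranked$inter_score >= 0 & ranked$inter_score <= 3))
  }
})

test_that("single-pair and vectorized scoring agree", {
  net <- random_network(99)
  ranked <- rank_pairs(net)
  i <- which.max(ranked$inter_score)
  one <- inter_score(net, ranked$drug_a[i], ranked$drug_b[i])
  expect_equal(one$inter_score, ranked$inter_score[i], tolerance = 1e-12)
})

test_that("ranking enumerates all pairs ascending with stable ties", {
  net <- random_network(3)
  n <- length(net$drugs)
  ranked <- rank_pairs(net)
  expect_equal(nrow(ranked), n * (n - 1) / 2)
  expect_true(all(diff(ranked$inter_score) >= 0))
  expect_true(all(ranked$drug_a < ranked$drug_b))
  # within tied scores, pairs are sorted lexicographically
  key <- paste(ranked$drug_a, ranked$drug_b)
  for (s in unique(ranked$inter_score)) {
    k <- key[ranked$inter_score == s]
    expect_equal(k, sort(k))
  }
  # shuffling the candidate drug order leaves the ranking unchanged
  shuffled <- rank_pairs(net, sample(net$drugs))
  expect_identical(ranked, shuffled)
})

test_that("negative selection is a positive-free prefix of the ranking", {
  net <- random_network(8)
  ranked <- rank_pairs(net)
  pos <- ranked[c(1, 2, 3), c("drug_a", "drug_b")]  # 3 lowest-ranked
  neg <- select_negatives(ranked, pos, nsr = 1)
  expect_equal(nrow(neg), 3L)
  # selection starts right after the skipped positives
  expect_equal(neg, ranked[4:6, c("drug_a", "drug_b")],
               ignore_attr = TRUE)
  both <- merge(neg, pos)
  expect_equal(nrow(both), 0L)

  pos10 <- ranked[seq(2, 20, 2), c("drug_a", "drug_b")]
  expect_equal(nrow(select_negatives(ranked, pos10, nsr = 0.5)), 5L)
  # round-half-to-even on fractional counts
  pos3 <- ranked[1:3, c("drug_a", "drug_b")]
  expect_equal(nrow(select_negatives(ranked, pos3, nsr = 0.5)), 2L)
  expect_error(select_negatives(ranked, pos3, nsr = 1e6),
               "capacity error")

  # extra exclusions are skipped without changing the requested count
  strict <- select_negatives(ranked, pos, nsr = 1,
                             exclude = ranked[4:5, c("drug_a", "drug_b")])
  expect_equal(strict, ranked[6:8, c("drug_a", "drug_b")],
               ignore_attr = TRUE)
})
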