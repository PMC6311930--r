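test_that("generator output is deterministic and correctly sized", {
  cfg <- synth_config(seed = 2)
  fx1 <- synth_generate(cfg)
  fx2 <- synth_generate(cfg)
  expect_identical(fx1$tables, fx2$tables)
  expect_identical(fx1$truth, fx2$truth)
  # 3 ADRs x 10 positives -> 30 DDAA rows
  expect_equal(nrow(fx1$tables$ddaa), 30L)
  expect_equal(nrow(fx1$truth$interacting_pairs), 30L)
  # planted positives are planted interacting pairs
  pk <- paste(fx1$truth$interacting_pairs$drug_a,
              fx1$truth$interacting_pairs$drug_b)
  expect_true(all(paste(fx1$tables$ddaa$drug_a,
                        fx1$tables$ddaa$drug_b) %in% pk))
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(n_drugs = 4, n_interacting_pairs = 10),
               "config error")
  expect_error(synth_config(n_positives_per_adr = 50,
                            n_interacting_pairs = 20), "config error")
  expect_error(synth_config(n_genes = 5), "config error")
  expect_error(synth_config(signal_strength = 1.2), "config error")
})

test_that("planted pairs share genes, diseases and a disease gene", {
  fx <- synth_generate(synth_config(seed = 14))
  obj <- fixture_objects(fx)
  net <- obj$network
  for (i in seq_len(nrow(fx$truth$interacting_pairs))) {
    a <- fx$truth$interacting_pairs$drug_a[i]
    b <- fx$truth$interacting_pairs$drug_b[i]
    ga <- net$drug_gene$right_id[net$drug_gene$left_id == a]
    gb <- net$drug_gene$right_id[net$drug_gene$left_id == b]
    da <- net$drug_disease$right_id[net$drug_disease$left_id == a]
    db <- net$drug_disease$right_id[net$drug_disease$left_id == b]
    shared_g <- intersect(ga, gb)
    shared_d <- intersect(da, db)
    expect_gte(length(shared_g), 1L)
    expect_gte(length(shared_d), 1L)
    dg <- net$disease_gene$right_id[net$disease_gene$left_id %in%
                                      shared_d]
    expect_gte(length(intersect(shared_g, dg)), 1L)
  }
})

test_that("noise-free ranking puts all non-planted pairs first", {
  fx <- synth_generate(synth_config(seed = 5, noise_rate = 0))
  obj <- fixture_objects(fx)
  ranked <- rank_pairs(obj$network, obj$catalog$drugs)
  pk <- paste(fx$truth$interacting_pairs$drug_a,
              fx$truth$interacting_pairs$drug_b)
  rk <- paste(ranked$drug_a, ranked$drug_b)
  planted_at <- match(pk, rk)
  n_nonplanted <- nrow(ranked) - length(pk)
  expect_true(all(planted_at > n_nonplanted))
  expect_equal(max(ranked$inter_score[-planted_at]), 0)
  expect_true(min(ranked$inter_score[planted_at]) > 0)
})

test_that("analytic separation bound holds on generated fixtures", {
  cfg <- synth_config(seed = 26, noise_rate = 0)
  sep <- expected_separation(cfg)
  expect_equal(sep$nonplanted_mean, 0)
  expect_gt(sep$gap, 0)
  fx <- synth_generate(cfg)
  obj <- fixture_objects(fx)
  ranked <- rank_pairs(obj$network, obj$catalog$drugs)
  pk <- paste(fx$truth$interacting_pairs$drug_a,
              fx$truth$interacting_pairs$drug_b)
  rk <- paste(ranked$drug_a, ranked$drug_b)
  expect_gte(min(ranked$inter_score[match(pk, rk)]),
             sep$planted_lower_bound - 1e-12)
  expect_error(expected_separation(synth_config(noise_rate = 0.1)),
               "unsupported")
})

test_that("moderate noise keeps the bottom quartile mostly non-planted", {
  fracs <- sapply(1:5, function(s) {
    fx <- synth_generate(synth_config(seed = s, noise_rate = 0.05))
    obj <- fixture_objects(fx)
    ranked <- rank_pairs(obj$network, obj$catalog$drugs)
    pk <- paste(fx$truth$interacting_pairs$drug_a,
                fx$truth$interacting_pairs$drug_b)
    q <- ranked[seq_len(floor(nrow(ranked) / 4)), ]
    mean(!(paste(q$drug_a, q$drug_b) %in% pk))
  })
  expect_gte(mean(fracs), 0.9)
})

test_that("fixtures round-trip through disk unchanged", {
  dir <- withr::local_tempdir()
  fx <- synth_generate(synth_config(seed = 19))
  write_fixture(fx, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_fixture(dir)
  direct <- fixture_objects(fx)
  expect_identical(back$catalog, direct$catalog)
  expect_equal(back$ddaa, direct$ddaa, ignore_attr = TRUE)
  sorted <- function(tab) {
    out <- tab[order(tab$left_id, tab$right_id), ]
    rownames(out) <- NULL
    out
  }
  expect_equal(sorted(back$network$drug_gene),
               sorted(direct$network$drug_gene))
  expect_equal(sorted(back$network$disease_gene),
               sorted(direct$network$disease_gene))
})
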