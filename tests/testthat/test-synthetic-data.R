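# Ground-truth maps, clone pools, selection and read simulation.

test_that("ground truth satisfies its class and score invariants", {
  truth <- generate_ground_truth(50, hyper_fraction = 0, seed = 2)
  v <- truth$variants

  # every substitution enumerated exactly once: 19 missense + nonsense + syn
  expect_equal(nrow(v), 50 * 21)
  expect_false(any(duplicated(v$key)))
  per_pos <- table(v$pos, v$class)
  expect_true(all(per_pos[, "missense"] == 19))
  expect_true(all(per_pos[, "nonsense"] == 1))
  expect_true(all(per_pos[, "synonymous"] == 1))

  expect_true(all(v$true_score[v$class == "synonymous"] == 1))
  ns <- v[v$class == "nonsense", ]
  expect_true(all(ns$true_score[ns$pos <= 50 - 14] == 0))
  expect_true(all(ns$true_score[ns$pos > 50 - 14] == 1))
  # zero hyper fraction: nothing above wild type
  expect_false(any(v$true_score > 1))

  # canonical codon changes translate to the annotated residue
  gc <- Biostrings::GENETIC_CODE
  expect_equal(unname(gc[v$codon_alt]), v$alt_aa)
  expect_true(all(v$codon_alt != v$codon_ref))
})

test_that("hyper-complementing fraction matches its target at full length", {
  truth <- generate_ground_truth(361, hyper_fraction = 0.025, seed = 9)
  v <- truth$variants
  mis <- v[v$class == "missense", ]
  frac <- mean(mis$true_score > 1)
  # binomial tolerance: 4 sd around 0.025 with n = 361 * 19
  tol <- 4 * sqrt(0.025 * 0.975 / nrow(mis))
  expect_lt(abs(frac - 0.025), tol)
  expect_true(all(mis$true_score[mis$true_score > 1] > 1))
})

test_that("ground truth is deterministic given the seed", {
  a <- generate_ground_truth(40, seed = 123)
  b <- generate_ground_truth(40, seed = 123)
  expect_identical(a$variants, b$variants)
  expect_identical(a$cds, b$cds)
  expect_false(identical(
    a$cds, generate_ground_truth(40, seed = 124)$cds))
})

test_that("invalid mixture weights are rejected", {
  expect_error(
    generate_ground_truth(40, bimodal_params = list(
      weights = c(0.5, 0.6), means = c(0, 1), sds = c(0.1, 0.1))),
    "mixture weights")
})

test_that("clone pool reproduces the configured mutational load", {
  truth <- generate_ground_truth(60, seed = 3)
  lib <- library_model(mean_variants_per_clone = 1.7, n_clones = 1e5)
  pool <- simulate_clone_pool(truth, lib, seed = 4)
  expect_lt(abs(mean(pool$clones$n_var) - 1.7), 0.02)

  # marginal frequencies: sum equals the abundance-weighted mean load, and
  # matches direct enumeration of the simulated pool
  direct <- sum(pool$clones$abundance * pool$clones$n_var)
  expect_equal(sum(pool$marginal$frequency), direct, tolerance = 1e-12)
  one <- pool$marginal$key[which.max(pool$marginal$frequency)]
  carriers <- pool$clone_variants$clone[pool$clone_variants$key == one]
  expect_equal(pool$marginal$frequency[pool$marginal$key == one],
               sum(pool$clones$abundance[carriers]), tolerance = 1e-12)
})

test_that("variant positions respect each clone's mutagenized region", {
  truth <- generate_ground_truth(40, seed = 3)
  lib <- library_model(n_clones = 3000,
                       region_bounds = list(c(1, 20), c(21, 40)))
  pool <- simulate_clone_pool(truth, lib, seed = 8)
  cv <- merge(pool$clone_variants,
              pool$clones[, c("clone", "region")], by = "clone")
  pos <- parse_key(cv$key)$pos
  expect_true(all(pos[cv$region == 1] <= 20))
  expect_true(all(pos[cv$region == 2] >= 21))
  expect_error(
    simulate_clone_pool(truth, library_model(
      n_clones = 10, region_bounds = list(c(1, 50))), 1),
    "region bounds")
})

test_that("vanishing mutational load gives an all-wild-type pool", {
  truth <- generate_ground_truth(30, seed = 3)
  lib <- library_model(mean_variants_per_clone = 1e-9, n_clones = 500)
  pool <- simulate_clone_pool(truth, lib, seed = 4)
  expect_true(all(pool$clones$n_var == 0))
  expect_equal(nrow(pool$marginal), 0)
})

test_that("selection leaves a uniformly fit pool unchanged", {
  truth <- generate_ground_truth(30, seed = 6)
  pool <- wt_control_pool(truth, n_clones = 5)
  pool$clones$abundance <- c(0.4, 0.3, 0.1, 0.15, 0.05)
  sel <- selection_model(generations = 5, stop_syn_growth_gap = 2,
                         noise_sd = 0)
  post <- simulate_selection(pool, truth, sel, seed = 1)
  expect_equal(post$clones$abundance, pool$clones$abundance,
               tolerance = 1e-12)
})

test_that("two-clone selection follows the closed-form growth ratio", {
  truth <- generate_ground_truth(30, seed = 6)
  v <- truth$variants
  null_key <- v$key[v$class == "nonsense" & v$true_score == 0][1]
  syn_key <- v$key[v$class == "synonymous"][1]
  pool <- structure(list(
    clones = data.frame(clone = 1:2, region = 1L, n_var = 1L,
                        abundance = c(0.5, 0.5)),
    clone_variants = data.table::as.data.table(
      list(clone = 1:2, key = c(null_key, syn_key))),
    marginal = data.frame(key = c(null_key, syn_key),
                          frequency = c(0.5, 0.5)),
    region_bounds = list(c(1L, 30L))), class = "clone_pool")
  g <- 0.8; t <- 3
  sel <- selection_model(generations = t, stop_syn_growth_gap = g,
                         noise_sd = 0)
  post <- simulate_selection(pool, truth, sel, seed = 1)
  ratio_pre <- pool$clones$abundance[2] / pool$clones$abundance[1]
  ratio_post <- post$clones$abundance[2] / post$clones$abundance[1]
  expect_equal(ratio_post / ratio_pre, exp(g * t), tolerance = 1e-9)
  # deterministic with zero noise and fixed seed
  post2 <- simulate_selection(pool, truth, sel, seed = 99)
  expect_equal(post$clones$abundance, post2$clones$abundance)
})

test_that("monotonicity: larger growth gap separates class medians more", {
  truth <- generate_ground_truth(30, seed = 6)
  lib <- library_model(n_clones = 2000,
                       region_bounds = list(c(1, 30)))
  pool <- simulate_clone_pool(truth, lib, seed = 2)
  seps <- vapply(c(0.5, 1, 2), function(gap) {
    sel <- selection_model(generations = 2, stop_syn_growth_gap = gap,
                           noise_sd = 0)
    post <- simulate_selection(pool, truth, sel, seed = 3)
    m <- merge(merge(post$marginal, pool$marginal, by = "key",
                     suffixes = c("_post", "_pre")),
               truth$variants[, c("key", "class", "pos")], by = "key")
    phi <- m$frequency_post / m$frequency_pre
    log(median(phi[m$class == "synonymous"])) -
      log(median(phi[m$class == "nonsense" & m$pos <= 16]))
  }, 0)
  expect_true(all(diff(seps) > 0))
})

test_that("error-free read pairs reproduce clone sequences exactly", {
  fx <- small_sim(per_base_error = 0, depth = 200)
  pairs <- materialize_pairs(fx$rps)
  # reconstruct each pair's expected sequence from its clone's edits
  pc <- fx$rps$pair_clone
  edits <- merge(fx$pool$clone_variants, fx$truth$nt_changes, by = "key",
                 allow.cartesian = TRUE)
  for (i in sample(nrow(pairs), 25)) {
    tile <- pairs$tile_id[i]; pr <- pairs$pair_id[i]
    cl <- pc$clone[pc$tile == tile & pc$pair == pr]
    off <- pairs$offset[i]
    expseq <- strsplit(substr(fx$truth$cds, off + 1, off + 30), "")[[1]]
    e <- edits[edits$clone == cl & edits$nt_pos >= off &
                 edits$nt_pos < off + 30, ]
    if (nrow(e)) expseq[e$nt_pos - off + 1] <- e$alt_base
    expect_identical(pairs$calls_fwd[i], paste(expseq, collapse = ""))
    expect_identical(pairs$calls_rev[i], pairs$calls_fwd[i])
  }
})

test_that("observed variant frequencies follow binomial sampling", {
  fx <- small_sim(per_base_error = 0, depth = 50000, n_clones = 300,
                  seed = 31)
  ct <- tabulate_pairs(fx$rps)
  m <- merge(ct, fx$pool$marginal, by = "key")
  # each observed count is within 5 binomial sd of depth * marginal
  expected <- 50000 * m$frequency.y
  sdev <- sqrt(pmax(expected * (1 - m$frequency.y), 1))
  expect_true(all(abs(m$count - expected) < 5 * sdev))
})

test_that("duplex-concordant background matches the double-error rate", {
  truth <- generate_ground_truth(30, seed = 5)
  wt <- wt_control_pool(truth)
  depth <- 50000
  count_bg <- function(e, seed) {
    seqm <- sequencing_model(depth_per_tile = depth, tile_length = 30,
                             per_base_error = e)
    ct <- tabulate_pairs(simulate_read_pairs(wt, seqm, truth, seed))
    sum(ct$count)
  }
  # expected concordant miscalls per tile: depth * length * e^2 / 3
  n1 <- count_bg(0.01, 11)
  n3 <- count_bg(0.03, 12)
  exp1 <- depth * 90 * 0.01^2 / 3
  exp3 <- depth * 90 * 0.03^2 / 3
  expect_lt(abs(n1 - exp1), 5 * sqrt(exp1))
  expect_lt(abs(n3 - exp3), 5 * sqrt(exp3))
  # quadratic suppression: tripling the error rate gives ~9x background
  expect_gt(n3 / n1, 5)
  expect_lt(n3 / n1, 14)
})

test_that("read simulation is deterministic given the seed", {
  fx1 <- small_sim(per_base_error = 0.01, seed = 77)
  fx2 <- small_sim(per_base_error = 0.01, seed = 77)
  expect_identical(as.data.frame(fx1$rps$records),
                   as.data.frame(fx2$rps$records))
})
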