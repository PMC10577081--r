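# Count filters, enrichment ratios, score anchoring, error regularization,
# map combination and preference transforms.

test_that("count and WT-percentile filters match brute-force application", {
  set.seed(1)
  keys <- ladder_keys(100, "V")
  counts <- rpois(100, 30)
  counts[1:10] <- 0:9               # below the raw-count threshold
  tab <- make_count_table(keys, counts)
  wt <- make_count_table(ladder_keys(40, "L"), rpois(40, 8))

  out <- filter_counts(tab, wt, min_count = 10, wt_percentile = 90)
  thresh <- quantile(wt$frequency, 0.9, names = FALSE)
  keep_oracle <- !(tab$count < 10 | tab$frequency < thresh)
  expect_setequal(out$key, tab$key[keep_oracle])
  log <- attr(out, "filter_log")
  expect_setequal(log$key, tab$key[!keep_oracle])
  # count 9 is removed, count 10 survives (given it passes the WT rule)
  expect_false("A10V" %in% out$key)

  # an all-zero WT library filters nothing by the percentile rule
  wt0 <- make_count_table(ladder_keys(5, "L"), rep(0L, 5))
  out0 <- filter_counts(tab, wt0, min_count = 0)
  expect_equal(nrow(out0), nrow(tab))

  expect_error(filter_counts(tab, tab[0, ]), "WT")
})

test_that("counts-per-million reading of the filter is available", {
  tab <- make_count_table(ladder_keys(3, "V"), c(5L, 15L, 120L),
                          depth = 1e6)
  wt0 <- make_count_table(ladder_keys(2, "L"), c(0L, 0L))
  out <- filter_counts(tab, wt0, min_cpm = 10)
  expect_setequal(out$key, c("A2V", "A3V"))
})

test_that("enrichment ratios subtract background and floor depleted variants", {
  keys <- ladder_keys(4, "V")
  ns <- make_count_table(keys, c(100L, 100L, 100L, 100L), depth = 10000L)
  s <- make_count_table(keys, c(200L, 50L, 10L, 100L), depth = 10000L,
                        condition = "select")
  wt_ns <- make_count_table(keys[3:4], c(2L, 150L), depth = 10000L)
  wt_s <- make_count_table(keys[3], 10L, depth = 10000L)

  enr <- adjust_and_enrich(s, ns, wt_s, wt_ns)
  enr <- enr[match(keys, enr$key), ]

  # no background: phi is the plain frequency ratio
  expect_equal(enr$phi[1], 2)
  expect_equal(enr$phi[2], 0.5)
  # selective frequency equal to its WT background: floored at 0.5 reads
  expect_equal(enr$f_s_adj[3], 0.5 / 10000)
  expect_true(enr$floored[3])
  expect_gt(enr$phi[3], 0)
  # non-positive adjusted non-selective frequency: unusable
  expect_false(enr$usable[4])
  expect_true(is.na(enr$phi[4]))

  # doubling depths (and counts) leaves phi unchanged
  double <- function(x) {
    x$count <- x$count * 2L; x$depth <- x$depth * 2L
    x$frequency <- x$count / x$depth
    x
  }
  enr2 <- adjust_and_enrich(double(s), double(ns), double(wt_s),
                            double(wt_ns))
  enr2 <- enr2[match(keys, enr2$key), ]
  expect_equal(enr2$phi[1:2], enr$phi[1:2])
})

test_that("selective-only variants are marked unusable", {
  ns <- make_count_table(ladder_keys(2, "V"), c(50L, 60L))
  s <- make_count_table(c(ladder_keys(2, "V"), "A9V"), c(40L, 30L, 20L),
                        condition = "select")
  enr <- adjust_and_enrich(s, ns, ns[0, ], ns[0, ])
  expect_false(enr$usable[enr$key == "A9V"])
})

test_that("scale medians follow their definitions and exclusions", {
  keys <- c(ladder_keys(3, "*"), ladder_keys(3, "A")[1:3])
  # nonsense phis 0.1/0.2/0.3 at positions 1..3; synonymous 1.0/1.2/1.4
  enr <- make_enrichment_table(
    c(make_key("A", 1:3, "*"), make_key("A", 4:6, "A")),
    c(0.1, 0.2, 0.3, 1.0, 1.2, 1.4))
  sc <- compute_scales(enr, protein_length = 40)
  expect_equal(sc$phi_stop, 0.2)
  expect_equal(sc$phi_syn, 1.2)

  # a nonsense variant 5 residues from the C terminus is excluded
  enr2 <- make_enrichment_table(
    c(make_key("A", c(1:3, 35), "*"), make_key("A", 4:6, "A")),
    c(0.1, 0.2, 0.3, 9.0, 1.0, 1.2, 1.4))
  sc2 <- compute_scales(enr2, protein_length = 40)
  expect_equal(sc2$phi_stop, 0.2)
  expect_equal(sc2$n_stop, 3)

  # selection that fails to separate the classes is a calibration error
  flat <- make_enrichment_table(
    c(make_key("A", 1:3, "*"), make_key("A", 4:6, "A")),
    c(1, 1, 1, 0.5, 1, 1.5))
  expect_error(compute_scales(flat, protein_length = 40), "calibration")
  expect_error(
    compute_scales(enr[1:4, ], protein_length = 40), "at least 3")
})

test_that("functional scores anchor at the class medians", {
  phi_stop <- 0.2; phi_syn <- 1.2
  enr <- make_enrichment_table(
    c(make_key("A", 1:3, "*"), make_key("A", 4:6, "A"),
      make_key("A", 7:9, "V")),
    c(0.1, phi_stop, 0.3, 1.0, phi_syn, 1.4,
      phi_syn, phi_stop, sqrt(phi_syn * phi_stop)))
  sc <- compute_scales(enr, protein_length = 40)
  scored <- functional_score(enr, sc)
  fs <- setNames(scored$fs, scored$key)
  expect_identical(unname(fs["A7V"]), 1)      # phi = synonymous median
  expect_identical(unname(fs["A8V"]), 0)      # phi = nonsense median
  expect_equal(unname(fs["A9V"]), 0.5)        # geometric midpoint
  # exact anchoring of the class medians themselves
  expect_identical(median(fs[1:3]), 0)
  expect_identical(median(fs[4:6]), 1)
})

test_that("error regularization blends toward the frequency trend", {
  # 60 variants with constant replicate scatter fix the trend; one variant
  # with identical replicates is shrunk toward it
  set.seed(8)
  n <- 60
  base <- runif(n, 0.2, 0.8)
  d <- 0.1
  rep_scores <- data.frame(
    key = rep(ladder_keys(n, "V"), each = 2),
    replicate = rep(1:2, n),
    fs = as.vector(rbind(base - d / 2, base + d / 2)),
    f_ns = rep(10^runif(n, -4, -2), each = 2))
  sd_i <- sd(c(-d / 2, d / 2))          # constant per-variant replicate sd
  trend <- sd_i / qnorm(0.75)

  # m = 0: plain empirical standard error of the mean
  est0 <- estimate_error(rep_scores, m = 0)
  expect_equal(est0$sigma, rep(sd_i / sqrt(2), n), tolerance = 1e-12)

  # identical replicates: sigma is the m/(m+n) blend of 0 and the trend
  extra <- data.frame(key = "C99C", replicate = 1:2, fs = c(0.5, 0.5),
                      f_ns = 1e-3)
  est <- estimate_error(rbind(rep_scores, extra), m = 2)
  got <- est$sigma[est$key == "C99C"]
  expected <- sqrt((2 * trend^2 + 2 * 0^2) / (2 + 2) / 2)
  expect_equal(got, expected, tolerance = 1e-9)

  # single-replicate variants take the trend value and are flagged
  single <- data.frame(key = "D88D", replicate = 1, fs = 0.4, f_ns = 1e-3)
  est1 <- estimate_error(rbind(rep_scores, single), m = 2)
  expect_true(est1$single_rep[est1$key == "D88D"])
  expect_equal(est1$sigma[est1$key == "D88D"], trend, tolerance = 1e-9)
})

test_that("quality filter boundaries read strictly", {
  sc <- data.frame(key = ladder_keys(4, "V"),
                   sigma = c(0.31, 0.3, 0.1, 0.1),
                   f_ns = c(1e-3, 1e-3, 4e-5, 5e-5))
  out <- quality_filter(sc)
  expect_equal(out$passed_filters, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("isoform rescaling fits the least-squares affine map", {
  set.seed(3)
  n <- 80
  fs_b <- runif(n)
  mk <- function(fs) data.frame(key = ladder_keys(n, "V"), fs = fs,
                                sigma = 0.1, passed_filters = TRUE)
  # identical maps: identity transform
  ident <- rescale_isoform(mk(fs_b), mk(fs_b))
  cf <- attr(ident, "rescale_coef")
  expect_equal(unname(cf["slope"]), 1, tolerance = 1e-9)
  expect_equal(unname(cf["intercept"]), 0, tolerance = 1e-9)

  # map_a = 2 * map_b: fitted slope 1/2
  scaled <- rescale_isoform(mk(2 * fs_b), mk(fs_b))
  expect_equal(unname(attr(scaled, "rescale_coef")["slope"]), 0.5,
               tolerance = 1e-9)
  expect_equal(scaled$fs, fs_b, tolerance = 1e-9)

  # monotone transform: rank correlation between maps unchanged
  a <- mk(fs_b + rnorm(n, 0, 0.05))
  before <- cor(a$fs, fs_b, method = "spearman")
  after <- cor(rescale_isoform(a, mk(fs_b))$fs, fs_b, method = "spearman")
  expect_equal(before, after)

  expect_error(rescale_isoform(mk(fs_b)[1:10, ], mk(fs_b)[1:10, ]),
               "shared")
  expect_error(rescale_isoform(mk(rep(0.5, n)), mk(fs_b)), "variance")
})

test_that("map combination is inverse-variance weighted with passthrough", {
  m1 <- data.frame(key = c("A1V", "A2V"), fs = c(0.8, 0.3),
                   sigma = c(0.1, 0.2), passed_filters = c(TRUE, TRUE))
  m2 <- data.frame(key = c("A1V", "A3V"), fs = c(0.4, 0.9),
                   sigma = c(0.2, 0.1), passed_filters = c(TRUE, TRUE))
  cmb <- combine_maps(m1, m2)
  both <- cmb[cmb$key == "A1V", ]
  # weights 100 and 25: (0.8*100 + 0.4*25) / 125 = 0.72
  expect_equal(both$fs_combined, 0.72)
  expect_equal(both$sigma_combined, sqrt(1 / 125))
  expect_equal(both$delta, 0.4)
  only2 <- cmb[cmb$key == "A3V", ]
  expect_equal(only2$fs_combined, 0.9)
  expect_equal(only2$sources, "map2")
  expect_true(is.na(only2$delta))

  # equal errors reduce to the simple mean
  e1 <- data.frame(key = "A1V", fs = 0.2, sigma = 0.1,
                   passed_filters = TRUE)
  e2 <- data.frame(key = "A1V", fs = 0.6, sigma = 0.1,
                   passed_filters = TRUE)
  expect_equal(combine_maps(e1, e2)$fs_combined, 0.4)

  expect_error(combine_maps(
    data.frame(key = "A1V", fs = 1, sigma = 0, passed_filters = TRUE),
    e2), "positive")
})

test_that("combination contracts hold over random inputs", {
  set.seed(11)
  for (i in 1:50) {
    fs <- runif(2, -0.5, 1.5)
    sg <- runif(2, 0.01, 0.4)
    m1 <- data.frame(key = "A1V", fs = fs[1], sigma = sg[1],
                     passed_filters = TRUE)
    m2 <- data.frame(key = "A1V", fs = fs[2], sigma = sg[2],
                     passed_filters = TRUE)
    cmb <- combine_maps(m1, m2)
    expect_gte(cmb$fs_combined, min(fs) - 1e-12)
    expect_lte(cmb$fs_combined, max(fs) + 1e-12)
    expect_lte(cmb$sigma_combined, min(sg))
  }
})

test_that("preference transforms implement the three hypotheses", {
  # identical scores: uniform preferences
  s <- matrix(0.7, nrow = 1, ncol = 20,
              dimnames = list(1, mavescore:::AA_ALPHABET))
  pref <- preference_transforms(s)
  for (p in pref) expect_equal(unname(p[1, ]), rep(1 / 20, 20))

  # damaging model inverts above-WT scores: {2, 1} -> {1/2, 1} -> {1/3, 2/3}
  two <- matrix(c(2, 1), nrow = 1)
  pd <- preference_transforms(two)
  expect_equal(unname(pd$damaging[1, ]), c(1 / 3, 2 / 3))
  expect_equal(unname(pd$neutral[1, ]), c(1 / 2, 1 / 2))
  expect_equal(unname(pd$advantageous[1, ]), c(2 / 3, 1 / 3))

  # with no score above 1 the three models coincide
  sub <- matrix(runif(40, 0, 1), nrow = 2)
  ps <- preference_transforms(sub)
  expect_equal(ps$advantageous, ps$neutral)
  expect_equal(ps$advantageous, ps$damaging)

  # rows always sum to 1; non-positive scores are clipped, not dropped
  withneg <- matrix(c(-1, 0, 2, 1), nrow = 2)
  pn <- preference_transforms(withneg)
  for (p in pn) expect_equal(unname(rowSums(p)), c(1, 1))
})

test_that("the scoring pipeline is deterministic", {
  truth <- generate_ground_truth(30, seed = 21)
  lib <- library_model(n_clones = 1500, region_bounds = list(c(1, 30)))
  seqm <- sequencing_model(depth_per_tile = 5000, tile_length = 45,
                           per_base_error = 0.001)
  sel <- selection_model(generations = 2)
  ex1 <- run_tile_experiment(truth, lib, seqm, sel, n_rep = 2, seed = 5)
  ex2 <- run_tile_experiment(truth, lib, seqm, sel, n_rep = 2, seed = 5)
  expect_identical(ex1$counts, ex2$counts)
})

test_that("two simulated isoforms of one truth agree after combination", {
  truth <- generate_ground_truth(60, seed = 31)
  lib <- library_model(n_clones = 30000)
  seqm <- sequencing_model(depth_per_tile = 200000, tile_length = 90,
                           per_base_error = 0.001)
  sel <- selection_model(generations = 3)
  res <- run_two_isoform_experiment(truth, lib, seqm, sel, n_rep = 2,
                                    seed = 41)
  shared <- merge(res$map_1[res$map_1$passed_filters, c("key", "fs")],
                  res$map_2[res$map_2$passed_filters, c("key", "fs")],
                  by = "key")
  expect_gt(nrow(shared), 1000)
  expect_gt(cor(shared$fs.x, shared$fs.y), 0.95)
  # combined scores sit between their inputs
  cmb <- merge(res$combined[res$combined$sources == "both", ], shared,
               by = "key")
  expect_true(all(cmb$fs_combined >= pmin(cmb$fs.x, cmb$fs.y) - 1e-9))
  expect_true(all(cmb$fs_combined <= pmax(cmb$fs.x, cmb$fs.y) + 1e-9))
})
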