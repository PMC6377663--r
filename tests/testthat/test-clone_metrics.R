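test_that("engraftment summary is clone count over injected cells", {
  p <- random_profile(250)
  expect_equal(engraftment_summary(p, 2500), list(n_clones = 250L,
                                                  efficiency = 0.1))
  expect_equal(engraftment_summary(clonal_profile("x", numeric(0)), 2500),
               list(n_clones = 0L, efficiency = 0))
  full <- random_profile(2500)
  expect_equal(engraftment_summary(full, 2500)$efficiency, 1)
})

test_that("cumulative clone distribution is a proper CDF over pooled clones", {
  curve <- cumulative_clone_distribution(make_profile(c(0.9, 0.1)))
  expect_equal(curve$frequency, c(0.1, 0.9))
  expect_equal(curve$cum_fraction, c(0.5, 1))

  one <- cumulative_clone_distribution(make_profile(c(0.5, 0.5)))
  expect_equal(max(one$frequency), 0.5)
  expect_equal(max(one$cum_fraction), 1)

  # two mice with identical profiles give the same curve shape as one
  p <- make_profile(c(0.6, 0.3, 0.1))
  two <- cumulative_clone_distribution(list(p, p))
  expect_equal(unique(two$frequency), c(0.1, 0.3, 0.6))
  expect_equal(two$cum_fraction, (1:6) / 6)

  set.seed(1)
  rand <- cumulative_clone_distribution(lapply(1:3, function(i)
    random_profile(40, paste0("m", i))))
  expect_true(all(diff(rand$cum_fraction) >= 0))
  expect_equal(rand$cum_fraction[nrow(rand)], 1)
  expect_error(cumulative_clone_distribution(clonal_profile("e", numeric(0))),
               "empty")
})

test_that("dispersion counts detection across pieces", {
  pieces <- list(
    make_profile(c(b1 = 1, b2 = 1), "p1"),
    make_profile(c(b1 = 1), "p2"),
    make_profile(c(b1 = 2, b3 = 1), "p3"),
    make_profile(c(b1 = 1), "p4"))
  d <- dispersion(pieces)
  expect_equal(d[["b1"]], 1.0)    # in all 4 pieces
  expect_equal(d[["b2"]], 0.25)
  expect_false("b9" %in% names(d))
  expect_true(all(d > 0 & d <= 1))
  expect_error(dispersion(pieces[1]), "single piece")
})

test_that("biomass representation sums tumor frequencies of shared clones", {
  tumor <- make_profile(c(B1 = 0.5, B2 = 0.3, B3 = 0.2), "tumor")
  distal <- make_profile(c(B1 = 0.9, B3 = 0.1), "lung")
  expect_equal(biomass_representation(tumor, distal), 0.7)
  expect_equal(biomass_representation(tumor, tumor), 1.0)
  disjoint <- make_profile(c(Z1 = 1), "blood")
  expect_equal(biomass_representation(tumor, disjoint), 0.0)
  set.seed(3)
  for (i in 1:10) {
    p <- random_profile(sample(5:80, 1))
    expect_equal(biomass_representation(p, p), 1)
  }
})

test_that("fold-change classes partition shared clones at the threshold", {
  tumor <- make_profile(c(B1 = 0.001, B2 = 0.1, B3 = 0.2, B4 = 0.699),
                        "tumor")
  distal <- make_profile(c(B1 = 0.02, B2 = 0.1, B3 = 0.01, B4 = 0.87),
                         "lung")
  fc <- fold_change_classify(tumor, distal, threshold = 10)
  cls <- setNames(fc$classes$class, fc$classes$barcode_id)
  expect_equal(cls[["B1"]], "over")          # ratio 20
  expect_equal(cls[["B2"]], "proportional")  # ratio 1
  expect_equal(cls[["B3"]], "under")         # ratio 0.05
  expect_equal(sum(fc$proportions), 1)
  expect_equal(nrow(fc$classes), 4L)

  # invariant to barcode ordering
  distal2 <- make_profile(rev(c(B1 = 0.02, B2 = 0.1, B3 = 0.01, B4 = 0.87)),
                          "lung")
  fc2 <- fold_change_classify(tumor, distal2)
  expect_equal(sort(fc$proportions), sort(fc2$proportions))

  none <- fold_change_classify(tumor, make_profile(c(Z = 1), "x"))
  expect_true(none$no_shared_barcodes)
  expect_error(fold_change_classify(tumor, distal, threshold = 1), "> 1")
})

test_that("diversity indices match closed forms and the vegan oracle", {
  u4 <- make_profile(rep(0.25, 4))
  d <- diversity_indices(u4)
  expect_equal(d$shannon, log(4))
  expect_equal(d$simpson, 0.25)
  single <- make_profile(c(b = 1))
  expect_equal(diversity_indices(single), list(shannon = 0, simpson = 1))
  for (k in c(10, 1000)) {
    dk <- diversity_indices(make_profile(rep(1 / k, k)))
    expect_equal(dk$shannon, log(k))
    expect_equal(dk$simpson, 1 / k)
  }
  # independent oracle on non-uniform profiles
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:5) {
    p <- random_profile(50)
    d <- diversity_indices(p, complement = TRUE)
    expect_equal(d$shannon,
                 unname(vegan::diversity(p$frequencies, "shannon")))
    expect_equal(d$simpson,
                 unname(vegan::diversity(p$frequencies, "simpson")))
  }
  # bounds: 0 <= H <= ln K, 1/K <= Simpson <= 1
  set.seed(6)
  for (i in 1:10) {
    p <- random_profile(sample(2:100, 1))
    d <- diversity_indices(p)
    k <- p$n_barcodes_detected
    expect_true(d$shannon >= 0 && d$shannon <= log(k) + 1e-12)
    expect_true(d$simpson >= 1 / k - 1e-12 && d$simpson <= 1)
  }
})

test_that("shared-barcode regression fits log10 frequencies of shared clones", {
  set.seed(9)
  a <- random_profile(50, "a")
  # lm warns about the essentially perfect fit; that is the point here
  cmp <- suppressWarnings(shared_barcode_regression(a, a))
  expect_equal(cmp$regression$slope, 1)
  expect_equal(cmp$regression$adj_r_squared, 1)

  # scaling by a constant over the shared set keeps slope 1 in log space
  b_freq <- a$frequencies[1:30]
  b <- clonal_profile("b", b_freq / sum(b_freq))
  cmp2 <- suppressWarnings(shared_barcode_regression(a, b))
  expect_equal(cmp2$regression$slope, 1, tolerance = 1e-9)
  expect_equal(length(cmp2$shared_barcodes), 30L)
  expect_equal(length(cmp2$a_only), 20L)

  few <- make_profile(c(bc001 = 0.5, bc002 = 0.5), "few")
  cmp3 <- shared_barcode_regression(a, few)
  expect_null(cmp3$regression)
  expect_true(cmp3$too_few_shared)
})

test_that("regression recovers a planted slope within 3 SE", {
  # Monte-Carlo oracle: log10 b = 0.8 * log10 a + gaussian(sd = 0.1)
  set.seed(123)
  n <- 100
  log_a <- runif(n, -6, -1)
  log_b <- 0.8 * log_a + rnorm(n, 0, 0.1)
  a <- clonal_profile("a", setNames(10^log_a / sum(10^log_a),
                                    sprintf("bc%03d", 1:n)))
  b <- clonal_profile("b", setNames(10^log_b / sum(10^log_b),
                                    sprintf("bc%03d", 1:n)))
  # renormalization shifts the intercept, never the slope
  cmp <- shared_barcode_regression(a, b)
  expect_lt(abs(cmp$regression$slope - 0.8), 3 * cmp$regression$slope_se)
})

test_that("organ overlap counts metastatic sites per tumor clone", {
  profs <- list(
    tumor = make_profile(c(B1 = 0.5, B2 = 0.3, B3 = 0.2), "t"),
    lung = make_profile(c(B1 = 0.5, B9 = 0.5), "l"),
    blood = make_profile(c(B1 = 0.9, B2 = 0.1), "b"),
    ovary = make_profile(c(B1 = 1), "o"))
  ov <- organ_overlap_counts(profs, "tumor")
  expect_equal(ov$sites_per_barcode[["B1"]], 3L)
  expect_equal(ov$sites_per_barcode[["B2"]], 1L)
  expect_equal(ov$sites_per_barcode[["B3"]], 0L)  # tumor only
  expect_equal(as.integer(ov$histogram[c("0", "1", "3")]), c(1L, 1L, 1L))
  expect_equal(ov$non_tumor_resident, "B9")
})

test_that("group comparison tests behave at identity and separation", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  id <- group_comparison_tests(x, x, mode = "welch_log")
  expect_equal(id$statistic, 0)
  expect_equal(id$p, 1)
  expect_error(group_comparison_tests(c(-1, 2), c(1, 2), mode = "welch_log"),
               "positive")

  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  ks <- group_comparison_tests(g, mode = "ks_pairwise_mean")
  expect_equal(ks$group_a$mean_p, 1)
  expect_equal(ks$group_a$n_pairs, 3L)

  set.seed(21)
  lo <- exp(rnorm(20, 0, 1))
  hi <- exp(rnorm(20, 5, 1))
  sep <- group_comparison_tests(lo, hi, mode = "welch_log")
  expect_lt(sep$p, 0.001)
  w <- group_comparison_tests(lo, hi, mode = "wilcoxon")
  expect_lt(w$p, 0.001)
})

test_that("tumor volume and cell estimates follow the caliper formula", {
  est <- estimate_tumor_cells(5, 12, mass_mg = 600)
  expect_equal(est$volume_mm3, 150)       # 25 * 12 / 2
  expect_equal(est$cell_estimate, 6e8)    # 600 mg * 1e6 cells/mg
  expect_equal(estimate_tumor_cells(3, 3)$volume_mm3, 27 / 2)
  expect_error(estimate_tumor_cells(10, 5), "max_diameter")
})

test_that("Poisson single-integration fraction matches the dpois oracle", {
  for (f in c(0.07, 0.10, 0.15, 0.20)) {
    res <- poisson_single_integration(f)
    m <- res$moi
    oracle <- dpois(1, m) / (1 - dpois(0, m))  # P(exactly 1 | >= 1)
    expect_equal(res$single_fraction, oracle)
    expect_equal(1 - dpois(0, m), f)  # moi reproduces the transduction rate
  }
  # the 10-20% transduction window gives the ~90-95% single-copy band
  band <- poisson_single_integration(c(0.10, 0.20))$single_fraction
  expect_true(all(band > 0.89 & band < 0.95))
  expect_error(poisson_single_integration(1), "in \\(0, 1\\)")
})
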