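test_that("ground truth respects its stated world", {
  cfg <- synthetic_config(seed = 3L)
  truth <- generate_ground_truth(cfg)
  expect_true(all(truth$seeders %in% truth$shedders))
  expect_true(all(truth$shedders %in% truth$engrafted))
  for (tt in truth$tissue_truth) {
    if (length(tt)) expect_lt(abs(sum(tt) - 1), 1e-9)
  }
  expect_equal(length(truth$sequences), 2500L)
  expect_true(all(nchar(truth$sequences) == 98L))

  # boundary configs
  all_in <- generate_ground_truth(synthetic_config(library_size = 100,
                                                   n_injected = 100,
                                                   engraft_prob = 1,
                                                   seed = 4))
  expect_equal(length(all_in$engrafted), 100L)
  no_seed <- generate_ground_truth(synthetic_config(seeder_fraction = 0,
                                                    seed = 5))
  expect_equal(length(no_seed$tissue_truth$lung_T3), 0L)

  # the heavy-tailed default spans orders of magnitude
  f <- truth$tissue_truth$tumor
  expect_gt(log10(max(f) / min(f)), 4)
})

test_that("generation is bit-reproducible given (cfg, seed)", {
  cfg <- synthetic_config(seed = 11L, spurious_barcode_rate = 1,
                          frac_low_depth = 0.2)
  t1 <- generate_ground_truth(cfg)
  t2 <- generate_ground_truth(cfg)
  expect_identical(t1$tissue_truth, t2$tissue_truth)
  expect_identical(t1$seeders, t2$seeders)
  m1 <- synthesize_counts(t1)
  m2 <- synthesize_counts(t2)
  expect_identical(m1$counts, m2$counts)
  expect_identical(m1$metadata, m2$metadata)
  t3 <- generate_ground_truth(synthetic_config(seed = 12L))
  expect_false(identical(t1$tissue_truth$tumor, t3$tissue_truth$tumor))
})

test_that("engraftment matches its binomial expectation over seeds", {
  counts <- vapply(1:200, function(s)
    length(generate_ground_truth(synthetic_config(seed = s))$engrafted),
    integer(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 250), 3 * se)
})

test_that("piece allocation is patchy with more pieces for larger clones", {
  truth <- generate_ground_truth(synthetic_config(seed = 21L))
  piece_names <- paste0("piece_", 1:8)
  presence <- sapply(truth$tissue_truth[piece_names],
                     function(p) truth$engrafted %in% names(p))
  n_pieces <- rowSums(presence)
  f <- truth$tissue_truth$tumor[truth$engrafted]
  expect_gt(cor(rank(f), n_pieces, method = "spearman"), 0.3)
  # contiguity on the chain: occupied pieces form one run
  runs <- apply(presence, 1, function(x) {
    r <- rle(x)
    sum(r$values)
  })
  expect_true(all(runs == 1))
})

test_that("noise-free deep counts recover truth support exactly post-QC", {
  cfg <- synthetic_config(library_size = 300, n_injected = 300,
                          engraft_prob = 0.1, clone_sdlog = 1,
                          mean_reads_per_replicate = 2e5,
                          spurious_barcode_rate = 0, frac_low_depth = 0,
                          seed = 31L)
  truth <- generate_ground_truth(cfg)
  res <- qc_pipeline(synthesize_counts(truth))
  for (tissue in c("tumor", "blood")) {
    prof <- res$profiles[[paste0("m1_", tissue)]]
    expect_equal(sort(names(prof$frequencies)),
                 sort(names(truth$tissue_truth[[tissue]])))
  }
})

test_that("spurious single-replicate barcodes are always filtered out", {
  cfg <- synthetic_config(library_size = 300, n_injected = 300,
                          engraft_prob = 0.1, clone_sdlog = 1,
                          mean_reads_per_replicate = 2e5,
                          spurious_barcode_rate = 3, seed = 32L)
  truth <- generate_ground_truth(cfg)
  bcm <- synthesize_counts(truth)
  spur <- attr(bcm, "spurious")
  expect_gt(nrow(spur), 0)
  res <- qc_pipeline(bcm)
  surviving <- unlist(lapply(res$profiles, function(p) names(p$frequencies)))
  expect_length(intersect(unique(spur$barcode_id), surviving), 0)
})

test_that("forcing all replicates shallow removes the whole experiment", {
  cfg <- synthetic_config(library_size = 200, n_injected = 200,
                          engraft_prob = 0.2, frac_low_depth = 1, seed = 33L)
  truth <- generate_ground_truth(cfg)
  res <- qc_pipeline(synthesize_counts(truth))
  expect_length(res$profiles, 0L)
  expect_gt(nrow(res$report), 0L)
})

test_that("T3 lung flags non-seeders absent and recovers planted seeders", {
  cfg <- synthetic_config(seed = 34L, seeder_fraction = 0.05,
                          mean_reads_per_replicate = 2e5)
  truth <- generate_ground_truth(cfg)
  res <- qc_pipeline(synthesize_counts(truth))
  tumor <- res$profiles[["m1_tumor"]]
  lung3 <- res$profiles[["m1_lung_T3"]]
  # only seeders can appear post-resection
  expect_true(all(names(lung3$frequencies) %in% truth$seeders))
  # planted over-represented seeders (truth ratio > 10) are recovered
  tr_t <- truth$tissue_truth$tumor
  tr_l <- truth$tissue_truth$lung_T3
  planted_over <- names(tr_l)[tr_l / tr_t[names(tr_l)] > 10]
  fc <- fold_change_classify(tumor, lung3, threshold = 10)
  # lung-only barcodes have infinite ratio: over-represented by definition
  called_over <- union(fc$classes$barcode_id[fc$classes$class == "over"],
                       setdiff(names(lung3$frequencies),
                               names(tumor$frequencies)))
  sens <- mean(planted_over %in% called_over)
  expect_gte(sens, 0.9)
})

test_that("rendered reads demultiplex back to the exact count matrix", {
  cfg <- synthetic_config(library_size = 40, n_injected = 40,
                          engraft_prob = 0.3, clone_sdlog = 1,
                          mean_reads_per_replicate = 200, seed = 35L)
  truth <- generate_ground_truth(cfg)
  bcm <- synthesize_counts(truth)
  fq <- tempfile(fileext = ".fastq")
  render_reads(bcm, truth, fq)
  lib <- barcode_library(truth$sequences)
  back <- demultiplex_and_count(fq, amplicon_design(), bcm$metadata, lib,
                                max_mismatch = 0)
  expect_equal(unname(back$counts[, colnames(bcm$counts)]),
               unname(bcm$counts))
  expect_equal(back$unassigned, 0L)
})

test_that("a synthetic experiment writes a complete text bundle", {
  cfg <- synthetic_config(library_size = 60, n_injected = 60,
                          engraft_prob = 0.2, mean_reads_per_replicate = 500,
                          seed = 36L)
  truth <- generate_ground_truth(cfg)
  dir <- file.path(tempdir(), "synth_bundle")
  paths <- write_synthetic_experiment(truth, dir)
  expect_true(all(file.exists(paths)))
  sheet <- parse_sample_sheet(paths[["sheet"]])
  expect_gt(nrow(sheet), 0)
  bcm <- read_count_matrix(paths[["counts"]])
  expect_identical(bcm$counts, synthesize_counts(truth)$counts)
  tr <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(tr$engrafted, truth$engrafted)
})
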