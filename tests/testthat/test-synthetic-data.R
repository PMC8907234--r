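test_that("toy annotation has the right spans, unique IDs, and is seeded", {
  spec <- serp_sim_spec(n_transcripts = 5L, orf_length = 100L)
  ann <- sim_annotation(spec, seed = 7L)

  expect_equal(nrow(ann$features), 5L)
  expect_equal(anyDuplicated(ann$features$transcript_id), 0L)
  expect_true(all(ann$features$end - ann$features$start + 1 == 300L))
  expect_equal(unname(nchar(ann$sequences)),
               3L * ann$features$length_codons)
  expect_true(all(startsWith(unname(ann$sequences), "ATG")))

  expect_identical(ann, sim_annotation(spec, seed = 7L))
  expect_false(identical(ann$sequences,
                         sim_annotation(spec, seed = 8L)$sequences))
})

test_that("annotation round-trips through GFF3 on disk byte-identically", {
  skip_if_not_installed("rtracklayer")
  spec <- serp_sim_spec(n_transcripts = 3L, orf_length = c(50L, 80L, 120L))
  ann <- sim_annotation(spec, seed = 1L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_annotation(ann, d1)
  p2 <- write_annotation(sim_annotation(spec, seed = 1L), d2)
  expect_identical(readLines(p1[["gff"]]), readLines(p2[["gff"]]))
  expect_identical(readLines(p1[["fasta"]]), readLines(p2[["fasta"]]))

  back <- read_annotation(p1[["gff"]])
  expect_equal(back$length_codons[match(ann$features$transcript_id,
                                        back$transcript_id)],
               ann$features$length_codons)
})

test_that("footprint generator rejects invalid specs", {
  expect_error(serp_sim_spec(enrichment_fold = 0.5), "enrichment_fold")
  expect_error(serp_sim_spec(orf_length = 5L), ">= 10")
  expect_error(serp_sim_spec(orf_length = 100L, onset_codon = 100L),
               "onset_codon")
})

test_that("simulated total counts match the NB parameterization", {
  spec <- serp_sim_spec(n_transcripts = 10L, orf_length = 200L,
                        onset_codon = NA, mean_depth = 5,
                        nb_dispersion = 0.3, n_replicates = 2L)
  sim <- sim_footprints(spec, seed = 42L)
  totals <- sim$tracks$count[sim$tracks$condition == "total"]

  mu <- 5; size <- 0.3
  nb_var <- mu + mu^2 / size
  se <- sqrt(nb_var / length(totals))
  expect_lt(abs(mean(totals) - mu), 3 * se)
  # variance should be near the NB value, far above Poisson
  expect_gt(var(totals), mu + 0.3 * mu^2 / size)

  # near-Poisson limit: variance/mean -> 1 as the size parameter grows
  spec_p <- serp_sim_spec(n_transcripts = 10L, orf_length = 200L,
                          onset_codon = NA, mean_depth = 5,
                          nb_dispersion = 1e6, n_replicates = 2L)
  cp <- sim_footprints(spec_p, seed = 42L)$tracks$count
  expect_lt(abs(var(cp) / mean(cp) - 1), 0.1)
})

test_that("footprint generator is a pure function of spec and seed", {
  spec <- step_spec(n = 3L)
  expect_identical(sim_footprints(spec, seed = 5L),
                   sim_footprints(spec, seed = 5L))
  expect_false(identical(sim_footprints(spec, seed = 5L)$tracks$count,
                         sim_footprints(spec, seed = 6L)$tracks$count))
})

test_that("IP counts step up at the onset codon and carry its library size", {
  spec <- step_spec(n = 1L, len = 400L, onset = 200L, fold = 4,
                    depth = 20, dispersion = 1e6, reps = 1L)
  sim <- sim_footprints(spec, seed = 3L)
  ip <- dplyr::filter(sim$tracks, condition == "IP")
  pre <- mean(ip$count[ip$codon < 200])
  post <- mean(ip$count[ip$codon >= 200])
  expect_gt(post / pre, 3)
  expect_lt(post / pre, 5)
  by_lib <- dplyr::distinct(sim$tracks, condition, replicate, library_size)
  sums <- dplyr::summarise(sim$tracks, s = sum(count),
                           .by = c(condition, replicate))
  expect_equal(by_lib$library_size[order(by_lib$condition, by_lib$replicate)],
               sums$s[order(sums$condition, sums$replicate)])
})

test_that("noise-free qPCR wells give exact folds under both treatments", {
  wells <- sim_qpcr_wells(true_fold = 4, ct_sd = 0, n_bio = 3L, seed = 1L)
  folds <- qpcr_folds(wells)
  expect_equal(folds$fold[folds$treatment == "cycloheximide"], rep(4, 3))
  expect_equal(folds$fold[folds$treatment == "puromycin"], rep(1, 3))

  null_wells <- sim_qpcr_wells(true_fold = 1, ct_sd = 0, n_bio = 3L, seed = 1L)
  expect_equal(qpcr_folds(null_wells)$fold, rep(1, 6))
})

test_that("qPCR generator warns for single biological replicates and is seeded", {
  expect_warning(sim_qpcr_wells(n_bio = 1L, seed = 1L), "paired")
  expect_identical(sim_qpcr_wells(seed = 2L), sim_qpcr_wells(seed = 2L))
})

test_that("iBAQ generator is seeded and neutral without injected effects", {
  sim <- sim_ibaq(n_proteins = 10L, batch_factors = 1, seed = 9L)
  expect_identical(sim, sim_ibaq(n_proteins = 10L, batch_factors = 1,
                                 seed = 9L))
  folds <- ibaq_foldchange(sim$ibaq, sim$meta, bait = sim$bait)
  mean_log2 <- dplyr::summarise(folds, m = mean(log2(fold)), .by = protein)
  expect_true(all(abs(mean_log2$m) < 0.5))
  expect_lt(abs(mean(mean_log2$m)), 0.15)
})

test_that("an injected iBAQ fold change of 0.25 is recovered within 20%", {
  truth <- tibble::tibble(protein = c("P001", "P002"), genotype = "mutant",
                          fold = 0.25)
  sim <- sim_ibaq(n_proteins = 10L, n_batches = 4L,
                  batch_factors = c(1, 2, 0.5, 1.5),
                  true_folds = truth, seed = 11L)
  folds <- ibaq_foldchange(sim$ibaq, sim$meta, bait = sim$bait)
  rec <- dplyr::summarise(folds, m = exp(mean(log(fold))), .by = protein)
  for (p in truth$protein) {
    expect_lt(abs(rec$m[rec$protein == p] / 0.25 - 1), 0.2)
  }
})

test_that("iBAQ generator refuses a fold change on the bait", {
  expect_error(
    sim_ibaq(true_folds = tibble::tibble(protein = "BAIT",
                                         genotype = "mutant", fold = 2)),
    "bait")
})
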