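toy_annotation <- tibble::tibble(transcript_id = "TX0001",
                                 length_codons = 10L)

test_that("nucleotide positions collapse onto the expected codons", {
  counts <- tibble::tibble(transcript_id = "TX0001",
                           pos_nt = c(1, 2, 3), count = c(1, 1, 1))
  track <- codon_counts(counts, toy_annotation, condition = "total")
  expect_equal(track$count[track$codon == 1], 3L)
  expect_equal(sum(track$count), 3L)
  expect_equal(nrow(track), 10L)  # zero-filled to the ORF length

  # position 31 -> codon 11, outside a 10-codon ORF: dropped and reported
  expect_message(
    track2 <- codon_counts(
      tibble::tibble(transcript_id = "TX0001", pos_nt = 31, count = 2),
      toy_annotation, condition = "total", library_size = 10),
    "Dropped 1")
  expect_equal(sum(track2$count), 0L)

  # 3 reads per nt uniformly -> 9 reads per codon
  uni <- tibble::tibble(transcript_id = "TX0001", pos_nt = 1:30, count = 3)
  track3 <- codon_counts(uni, toy_annotation, condition = "IP")
  expect_equal(track3$count, rep(9L, 10))
})

test_that("P-site offset shifts codon assignment and bad input errors", {
  counts <- tibble::tibble(transcript_id = "TX0001", pos_nt = 1, count = 1)
  shifted <- codon_counts(counts, toy_annotation, condition = "IP",
                          psite_offset = 3)
  expect_equal(shifted$count[shifted$codon == 2], 1L)

  expect_error(
    codon_counts(tibble::tibble(transcript_id = "ghost", pos_nt = 1,
                                count = 1),
                 toy_annotation, condition = "IP"),
    "ghost")
  expect_error(
    codon_counts(tibble::tibble(transcript_id = "TX0001", pos_nt = 1.5,
                                count = 1),
                 toy_annotation, condition = "IP"),
    "line")
})

test_that("RPM normalization follows the scaling law", {
  track <- tibble::tibble(transcript_id = "t", condition = "IP",
                          replicate = 1L, codon = 1:3,
                          count = c(2L, 0L, 2L), library_size = 1e6)
  expect_equal(normalize_rpm(track)$density, c(2, 0, 2))
  expect_equal(normalize_rpm(dplyr::mutate(track, library_size = 2e6))$density,
               c(1, 0, 1))
  expect_equal(
    normalize_rpm(tibble::tibble(transcript_id = "t", condition = "IP",
                                 replicate = 1L, codon = 1L, count = 5L,
                                 library_size = 2e6))$density, 2.5)
  expect_error(normalize_rpm(dplyr::mutate(track, library_size = 0)),
               "positive")
})

test_that("replicate combination averages RPM densities", {
  two_reps <- tibble::tibble(
    transcript_id = "t", condition = "IP",
    replicate = rep(1:2, each = 2),
    codon = rep(1:2, 2),
    count = c(0L, 2L, 4L, 2L),
    library_size = 1e6)
  combined <- combine_replicates(two_reps)
  expect_equal(combined$density[order(combined$codon)], c(2, 2))
  expect_equal(unique(combined$n_replicates), 2L)

  # identical replicates leave the density unchanged; one replicate is a no-op
  one <- dplyr::filter(two_reps, replicate == 1)
  expect_equal(combine_replicates(one)$density[order(combine_replicates(one)$codon)],
               c(0, 2))
  expect_error(
    combine_replicates(dplyr::bind_rows(
      one, dplyr::mutate(dplyr::slice(one, 1), replicate = 2L))),
    "length")
})

test_that("gliding average matches the brute-force windowed mean", {
  expect_equal(gliding_average(c(0, 3, 0, 3, 0), 3), c(1.5, 1, 2, 1, 1.5))
  expect_equal(gliding_average(rep(2.5, 20), 7), rep(2.5, 20))
  expect_equal(gliding_average(1:10, 1), 1:10)
  expect_error(gliding_average(1:10, 4), "odd")

  withr::with_seed(99L, {
    for (i in 1:20) {
      x <- rnorm(sample(5:60, 1))
      w <- sample(c(1, 3, 5, 9, 15), 1)
      expect_equal(gliding_average(x, w), brute_gliding_average(x, w))
    }
  })
})

test_that("enrichment is 1 for identical tracks and k for proportional ones", {
  combined <- tibble::tibble(
    transcript_id = "t",
    condition = rep(c("IP", "total"), each = 20),
    codon = rep(1:20, 2),
    density = rep(5, 40),
    n_replicates = 1L)
  prof <- enrichment_profile(combined, window = 5, pseudocount = 0)
  expect_equal(prof$enrichment, rep(1, 20))

  prop <- dplyr::mutate(combined,
                        density = ifelse(condition == "IP", 15, 5))
  prof_k <- enrichment_profile(prop, window = 5, pseudocount = 1e-9)
  expect_equal(prof_k$enrichment, rep(3, 20), tolerance = 1e-6)

  zero_total <- dplyr::mutate(combined,
                              density = ifelse(condition == "total", 0, 5))
  expect_error(enrichment_profile(zero_total, window = 5, pseudocount = 0),
               "pseudocount")
})

test_that("enrichment is invariant to rescaling either library's size", {
  spec <- step_spec(n = 2L, len = 150L, onset = 60L, reps = 2L)
  tracks <- sim_footprints(spec, seed = 21L)$tracks
  prof <- serp_enrichment(tracks, window = 15, pseudocount = 1e-9)
  rescaled <- dplyr::mutate(
    tracks,
    library_size = ifelse(condition == "IP", library_size * 10, library_size))
  prof_r <- serp_enrichment(rescaled, window = 15, pseudocount = 1e-9)
  # RPM cancels through a vanishing pseudocount up to the 10x density shift
  expect_equal(prof_r$enrichment * 10, prof$enrichment, tolerance = 1e-3)
})

test_that("combining then smoothing commutes with smoothing then averaging", {
  spec <- step_spec(n = 1L, len = 120L, onset = 40L, reps = 3L)
  tracks <- sim_footprints(spec, seed = 8L)$tracks
  combined_first <- serp_enrichment(tracks, window = 9, pseudocount = 0.5)

  per_rep <- tracks |>
    normalize_rpm() |>
    dplyr::summarise(
      density = mean(density), .by = c(transcript_id, condition, codon))
  # per-replicate smoothing then averaging (linearity of both operators)
  smooth_first <- tracks |>
    normalize_rpm() |>
    dplyr::group_by(transcript_id, condition, replicate) |>
    dplyr::arrange(codon, .by_group = TRUE) |>
    dplyr::mutate(smooth = gliding_average(density, 9)) |>
    dplyr::group_by(transcript_id, condition, codon) |>
    dplyr::summarise(smooth = mean(smooth), .groups = "drop")
  ip <- dplyr::filter(smooth_first, condition == "IP")
  tot <- dplyr::filter(smooth_first, condition == "total")
  manual_E <- (ip$smooth[order(ip$codon)] + 0.5) /
    (tot$smooth[order(tot$codon)] + 0.5)
  expect_equal(combined_first$enrichment, manual_E)
})

test_that("a simulated step yields the expected post/pre enrichment ratio", {
  spec <- serp_sim_spec(n_transcripts = 1L, orf_length = 150L,
                        onset_codon = 50L, enrichment_fold = 4,
                        mean_depth = 50, nb_dispersion = 5,
                        n_replicates = 4L)
  tracks <- sim_footprints(spec, seed = 123L)$tracks
  prof <- serp_enrichment(tracks, window = 15, pseudocount = 0.5)
  ratio <- mean(prof$enrichment[prof$codon %in% 60:90]) /
    mean(prof$enrichment[prof$codon %in% 1:40])
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})
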