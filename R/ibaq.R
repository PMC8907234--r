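#' Median-normalize an iBAQ intensity table
#'
#' Scales each sample so that its median intensity over the detected
#' protein set equals the grand median (the median of the per-sample
#' medians). The detected set defaults to proteins with positive intensity
#' in every sample, so a protein dropping out of one sample does not skew
#' another sample's scale; `detected = "per_sample"` instead uses each
#' sample's own nonzero proteins.
#'
#' @param ibaq Long tibble `protein`, `sample`, `intensity` (>= 0).
#' @param detected `"all_samples"` (default) or `"per_sample"`.
#' @return The input tibble with normalized `intensity` and a
#'   `median_factor` column recording the applied per-sample factor.
#' @export
median_normalize <- function(ibaq, detected = c("all_samples", "per_sample")) {
  detected <- match.arg(detected)
  check_columns(ibaq, c("protein", "sample", "intensity"), "ibaq")
  if (any(ibaq$intensity < 0)) abort("Intensities must be non-negative.")
  positive <- ibaq |>
    dplyr::summarise(any_pos = any(.data$intensity > 0), .by = "sample")
  if (!all(positive$any_pos)) {
    abort(sprintf("Sample(s) with no positive intensity: %s.",
                  paste(positive$sample[!positive$any_pos], collapse = ", ")))
  }

  if (detected == "all_samples") {
    det <- ibaq |>
      dplyr::summarise(det = all(.data$intensity > 0), .by = "protein")
    det_set <- det$protein[det$det]
    if (!length(det_set)) {
      abort("No protein is detected (positive) in all samples.")
    }
    meds <- ibaq |>
      dplyr::filter(.data$protein %in% det_set) |>
      dplyr::summarise(med = median(.data$intensity), .by = "sample")
  } else {
    meds <- ibaq |>
      dplyr::filter(.data$intensity > 0) |>
      dplyr::summarise(med = median(.data$intensity), .by = "sample")
  }
  grand <- median(meds$med)
  ibaq |>
    dplyr::left_join(meds, by = "sample") |>
    dplyr::mutate(median_factor = grand / .data$med,
                  intensity = .data$intensity * .data$median_factor) |>
    dplyr::select(-"med")
}

#' Normalize an iBAQ table to the bait protein
#'
#' Divides every intensity by the sample's bait intensity, so the bait row
#' becomes 1 in every retained sample. Samples in which the bait is zero or
#' missing cannot be normalized and are excluded with a warning.
#'
#' @inheritParams median_normalize
#' @param bait Bait protein identifier.
#' @return The tibble with bait-relative intensities.
#' @export
bait_normalize <- function(ibaq, bait) {
  check_columns(ibaq, c("protein", "sample", "intensity"), "ibaq")
  bait_rows <- ibaq |>
    dplyr::filter(.data$protein == bait) |>
    dplyr::select("sample", bait_intensity = "intensity")
  if (!nrow(bait_rows)) {
    abort(sprintf("Bait protein '%s' is absent from the table.", bait))
  }
  joined <- ibaq |>
    dplyr::left_join(bait_rows, by = "sample")
  bad <- is.na(joined$bait_intensity) | joined$bait_intensity <= 0
  if (any(bad)) {
    excluded <- unique(joined$sample[bad])
    warn(sprintf("Excluding sample(s) with zero/missing bait: %s.",
                 paste(excluded, collapse = ", ")))
    joined <- joined[!joined$sample %in% excluded, , drop = FALSE]
    if (!nrow(joined)) abort("No sample retains a positive bait intensity.")
  }
  joined |>
    dplyr::mutate(intensity = .data$intensity / .data$bait_intensity) |>
    dplyr::select(-"bait_intensity")
}

#' Mutant-vs-wildtype fold changes, stratified by batch
#'
#' For every non-wildtype sample, each protein's normalized value is
#' divided by the mean of the same protein's normalized values in the
#' wildtype sample(s) of the same batch, so batch-wide multiplicative
#' effects cancel.
#'
#' @param ibaq_norm Normalized long tibble `protein`, `sample`, `intensity`
#'   (typically after [median_normalize()] and [bait_normalize()]).
#' @param meta Tibble `sample`, `genotype`, `batch`; wildtype samples have
#'   `genotype == "wildtype"`.
#' @return Tibble `protein`, `sample`, `genotype`, `batch`, `fold`.
#' @export
mutant_vs_wt_fold <- function(ibaq_norm, meta) {
  check_columns(ibaq_norm, c("protein", "sample", "intensity"), "ibaq_norm")
  check_columns(meta, c("sample", "genotype", "batch"), "meta")
  long <- ibaq_norm |>
    dplyr::inner_join(meta, by = "sample")

  wt <- long |>
    dplyr::filter(.data$genotype == "wildtype") |>
    dplyr::summarise(wt_value = mean(.data$intensity),
                     .by = c("protein", "batch"))
  mut <- long |>
    dplyr::filter(.data$genotype != "wildtype")
  missing_batches <- setdiff(unique(mut$batch), unique(wt$batch))
  if (length(missing_batches)) {
    abort(sprintf("No wildtype partner sample in batch(es): %s.",
                  paste(missing_batches, collapse = ", ")))
  }
  mut |>
    dplyr::left_join(wt, by = c("protein", "batch")) |>
    dplyr::mutate(fold = .data$intensity / .data$wt_value) |>
    dplyr::select("protein", "sample", "genotype", "batch", "fold")
}

#' Full iBAQ fold-change chain
#'
#' Median normalization, bait normalization and batch-stratified
#' mutant-vs-wildtype fold changes in one call.
#'
#' @inheritParams median_normalize
#' @inheritParams bait_normalize
#' @inheritParams mutant_vs_wt_fold
#' @return Tibble of per-protein, per-mutant-sample fold changes (see
#'   [mutant_vs_wt_fold()]).
#' @export
ibaq_foldchange <- function(ibaq, meta, bait,
                            detected = c("all_samples", "per_sample")) {
  ibaq |>
    median_normalize(detected = detected) |>
    bait_normalize(bait = bait) |>
    mutant_vs_wt_fold(meta = meta)
}

#' Compare fold changes between two protein groups
#'
#' Pools the log2 fold changes of the proteins in each group and, when both
#' groups contribute more than `min_n` values, compares them with a
#' two-sided unpaired t-test; otherwise only descriptive medians are
#' reported and the result is flagged as untested.
#'
#' @param folds Fold-change tibble with `protein` and `fold` (e.g. from
#'   [ibaq_foldchange()]).
#' @param group_a,group_b Character vectors of protein identifiers; the
#'   groups must not overlap.
#' @param min_n Minimum group size; a t-test is run only when both groups
#'   have strictly more than `min_n` log2-fold values.
#' @return One-row tibble: `n_a`, `n_b`, `median_fold_a`, `median_fold_b`,
#'   `mean_log2_a`, `mean_log2_b`, `t`, `p_value`, `tested`.
#' @export
group_compare <- function(folds, group_a, group_b, min_n = 4L) {
  check_columns(folds, c("protein", "fold"), "folds")
  if (!length(group_a) || !length(group_b)) {
    abort("Both groups must contain at least one protein.")
  }
  if (length(intersect(group_a, group_b))) {
    abort("Groups must not overlap.")
  }
  a <- log2(folds$fold[folds$protein %in% group_a])
  b <- log2(folds$fold[folds$protein %in% group_b])
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (!length(a) || !length(b)) {
    abort("Both groups must contribute at least one finite fold change.")
  }
  tested <- length(a) > min_n && length(b) > min_n
  if (tested) {
    tt <- t.test(a, b, paired = FALSE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    t_stat <- NA_real_
    p <- NA_real_
  }
  tibble(
    n_a = length(a), n_b = length(b),
    median_fold_a = median(2^a), median_fold_b = median(2^b),
    mean_log2_a = mean(a), mean_log2_b = mean(b),
    t = t_stat, p_value = p, tested = tested)
}

#' Read an iBAQ intensity matrix from TSV
#'
#' Expects a wide TSV with a `protein` column and one column per sample;
#' returns the long tidy form used by the normalization functions.
#'
#' @param path Path to the TSV.
#' @return Long tibble `protein`, `sample`, `intensity`.
#' @export
read_ibaq <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(wide, "protein", "ibaq table")
  tidyr::pivot_longer(wide, -"protein", names_to = "sample",
                      values_to = "intensity")
}
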