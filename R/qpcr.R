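#' Summarize a technical qPCR replicate group
#'
#' Applies the technical-replicate quality rule: a well whose Ct deviates
#' from the median of the remaining wells by more than `max_dev` cycles is
#' omitted (worst offender first, re-checking after each omission); a group
#' that would need two or more omissions, or has fewer than two wells to
#' begin with, fails quality control and the biological replicate is
#' excluded.
#'
#' @param ct Numeric vector of technical-replicate Ct values (cycles).
#' @param max_dev Maximum tolerated deviation from the median of the other
#'   wells, in Ct cycles.
#' @return A list: `mean_ct` (mean of retained wells, `NA` on QC failure),
#'   `omitted` (indices of omitted wells), `qc_pass`, `flag` (`TRUE` when
#'   any well was omitted).
#' @export
summarize_technical <- function(ct, max_dev = 0.5) {
  check_number(max_dev, "max_dev", lower = 0)
  if (length(ct) < 2 || any(is.na(ct))) {
    return(list(mean_ct = NA_real_, omitted = integer(0), qc_pass = FALSE,
                flag = TRUE))
  }
  keep <- seq_along(ct)
  omitted <- integer(0)
  repeat {
    if (length(keep) < 2) break
    dev <- vapply(seq_along(keep), function(i) {
      abs(ct[keep[i]] - median(ct[keep[-i]]))
    }, numeric(1))
    if (max(dev) <= max_dev) break
    worst <- keep[which.max(dev)]
    omitted <- c(omitted, worst)
    keep <- setdiff(keep, worst)
    if (length(omitted) >= 2) {
      return(list(mean_ct = NA_real_, omitted = omitted, qc_pass = FALSE,
                  flag = TRUE))
    }
  }
  list(mean_ct = mean(ct[keep]), omitted = omitted, qc_pass = TRUE,
       flag = length(omitted) > 0)
}

#' Summarize a well table over technical replicates
#'
#' Applies [summarize_technical()] to every `(bait, target, treatment,
#' bio_rep)` group of a well table.
#'
#' @param wells Tibble `bait`, `target_mrna`, `treatment`, `bio_rep`,
#'   `tech_rep`, `ct` (e.g. from [sim_qpcr_wells()] or
#'   [read_qpcr_wells()]).
#' @param max_dev Technical-outlier threshold in Ct cycles.
#' @return Tibble `bait`, `target_mrna`, `treatment`, `bio_rep`, `mean_ct`,
#'   `qc_pass`, `n_omitted`.
#' @export
summarize_wells <- function(wells, max_dev = 0.5) {
  check_columns(wells, c("bait", "target_mrna", "treatment", "bio_rep", "ct"),
                "wells")
  if (any(!is.na(wells$ct) & wells$ct <= 0)) {
    abort("Ct values must be positive.")
  }
  wells |>
    dplyr::reframe({
      s <- summarize_technical(.data$ct, max_dev = max_dev)
      tibble(mean_ct = s$mean_ct, qc_pass = s$qc_pass,
             n_omitted = length(s$omitted))
    }, .by = c("bait", "target_mrna", "treatment", "bio_rep"))
}

#' Fold enrichment from a Ct pair
#'
#' `f = efficiency ^ (control_ct - bait_ct)`: the bait's amplification
#' advantage over the no-bait background, expressed as a fold. Adding a
#' constant to both Cts leaves `f` unchanged (delta-Ct construction).
#'
#' @param bait_ct Mean Ct of the bait pull-down (vectorised).
#' @param control_ct Mean Ct of the matched no-bait control.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Fold enrichment(s), > 0.
#' @export
fold_enrichment <- function(bait_ct, control_ct, efficiency = 2) {
  check_number(efficiency, "efficiency", lower = 1 + 1e-9)
  efficiency^(control_ct - bait_ct)
}

#' Per-biological-replicate fold enrichments from a well table
#'
#' Summarizes technical replicates, drops QC-failed biological replicates,
#' and converts each bait Ct into a fold over the no-bait control of the
#' same target, treatment and biological replicate.
#'
#' @inheritParams summarize_wells
#' @param efficiency Amplification efficiency per cycle.
#' @param control_bait Label of the no-bait control in the `bait` column.
#' @return Tibble `bait`, `target_mrna`, `treatment`, `bio_rep`, `fold`,
#'   `flag` (technical omission in either well group).
#' @export
qpcr_folds <- function(wells, max_dev = 0.5, efficiency = 2,
                       control_bait = "no-bait") {
  summarized <- summarize_wells(wells, max_dev = max_dev)
  controls <- summarized |>
    dplyr::filter(.data$bait == control_bait, .data$qc_pass) |>
    dplyr::select("target_mrna", "treatment", "bio_rep",
                  control_ct = "mean_ct", control_omitted = "n_omitted")
  baits <- summarized |>
    dplyr::filter(.data$bait != control_bait, .data$qc_pass)
  if (!nrow(controls)) {
    abort(sprintf("No QC-passing '%s' control wells found.", control_bait))
  }
  joined <- baits |>
    dplyr::left_join(controls, by = c("target_mrna", "treatment", "bio_rep"))
  if (anyNA(joined$control_ct)) {
    miss <- joined |>
      dplyr::filter(is.na(.data$control_ct)) |>
      dplyr::distinct(.data$target_mrna, .data$treatment, .data$bio_rep)
    abort(sprintf(
      "Missing no-bait control for %d (target, treatment, bio_rep) group(s), e.g. %s / %s / %s.",
      nrow(miss), miss$target_mrna[1], miss$treatment[1], miss$bio_rep[1]))
  }
  joined |>
    dplyr::mutate(
      fold = fold_enrichment(.data$mean_ct, .data$control_ct, efficiency),
      flag = .data$n_omitted > 0 | .data$control_omitted > 0) |>
    dplyr::select("bait", "target_mrna", "treatment", "bio_rep", "fold",
                  "flag")
}

#' Two-criterion co-translational decision rule
#'
#' A bait-target pair is called co-translational when (I) the mean
#' cycloheximide fold enrichment is at or above the signal threshold
#' (default 1.5, inclusive) and (II) the signal decreases significantly
#' upon puromycin treatment: a two-sided paired t-test (paired by
#' biological replicate) with `p < alpha` and a CHX mean exceeding the
#' puromycin mean. If the fold vectors cannot be paired (unequal lengths),
#' a two-sided unpaired t-test is used instead, with a warning. Identical
#' paired differences are degenerate for the t-statistic and are resolved
#' by the sign of the common difference: all-zero differences are reported
#' as non-significant (`p = 1`), a constant non-zero difference as fully
#' significant (`p = 0`).
#'
#' @param chx_folds Per-biological-replicate folds under cycloheximide.
#' @param puro_folds Per-biological-replicate folds under puromycin, in the
#'   same biological-replicate order when paired.
#' @param threshold Signal threshold tau on the mean CHX fold (default 1.5).
#' @param alpha Significance level of the puromycin-decrease test.
#' @return A one-row tibble: `n_chx`, `n_puro`, `mean_chx`, `mean_puro`,
#'   `p_value`, `test` (`"paired"`/`"unpaired"`), `threshold`, `alpha`,
#'   `above_threshold`, `significant_decrease`, `co_translational`.
#' @export
call_cotranslational <- function(chx_folds, puro_folds, threshold = 1.5,
                                 alpha = 0.05) {
  check_number(threshold, "threshold", lower = 0)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  if (length(chx_folds) < 2 || length(puro_folds) < 2) {
    abort("At least 2 biological replicates per treatment are required.")
  }
  if (any(c(chx_folds, puro_folds) <= 0)) {
    abort("Fold enrichments must be positive.")
  }

  paired <- length(chx_folds) == length(puro_folds)
  if (!paired) {
    warn("Unequal replicate numbers: falling back to a two-sided unpaired t-test.")
    p <- t.test(chx_folds, puro_folds, paired = FALSE)$p.value
  } else {
    diffs <- chx_folds - puro_folds
    if (sd(diffs) <= 1e-9 * max(abs(diffs), 1)) {
      # numerically constant differences: the t statistic is undefined
      p <- if (isTRUE(all.equal(mean(diffs), 0))) 1 else 0
    } else {
      p <- t.test(chx_folds, puro_folds, paired = TRUE)$p.value
    }
  }

  mean_chx <- mean(chx_folds)
  mean_puro <- mean(puro_folds)
  above <- mean_chx >= threshold
  decrease <- p < alpha && mean_chx > mean_puro
  tibble(
    n_chx = length(chx_folds),
    n_puro = length(puro_folds),
    mean_chx = mean_chx,
    mean_puro = mean_puro,
    p_value = p,
    test = if (paired) "paired" else "unpaired",
    threshold = threshold,
    alpha = alpha,
    above_threshold = above,
    significant_decrease = decrease,
    co_translational = above && decrease)
}

#' Full RIP-qPCR pipeline: wells to co-translational calls
#'
#' Chains [summarize_wells()], [qpcr_folds()] and [call_cotranslational()]
#' for every bait-target pair in a well table.
#'
#' @inheritParams qpcr_folds
#' @inheritParams call_cotranslational
#' @return A `qpcr_calls` tibble, one row per (bait, target), with the
#'   columns of [call_cotranslational()]; the per-replicate folds are
#'   attached as the `folds` attribute.
#' @export
qpcr_calls <- function(wells, threshold = 1.5, alpha = 0.05, max_dev = 0.5,
                       efficiency = 2, control_bait = "no-bait") {
  folds <- qpcr_folds(wells, max_dev = max_dev, efficiency = efficiency,
                      control_bait = control_bait)
  calls <- folds |>
    dplyr::reframe({
      fold_by_rep <- tidyr::pivot_wider(
        dplyr::select(dplyr::pick(dplyr::everything()),
                      "treatment", "bio_rep", "fold"),
        names_from = "treatment", values_from = "fold")
      complete <- !is.na(fold_by_rep$cycloheximide) &
        !is.na(fold_by_rep$puromycin)
      call_cotranslational(fold_by_rep$cycloheximide[complete],
                           fold_by_rep$puromycin[complete],
                           threshold = threshold, alpha = alpha)
    }, .by = c("bait", "target_mrna"))
  structure(calls, class = c("qpcr_calls", class(calls)), folds = folds)
}

#' Read a RIP-qPCR well table from CSV
#'
#' Expects columns `bait`, `target_mrna`, `treatment`, `bio_rep`,
#' `tech_rep`, `ct`.
#'
#' @param path Path to a CSV file.
#' @return A well tibble suitable for [qpcr_calls()].
#' @export
read_qpcr_wells <- function(path) {
  wells <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(wells, c("bait", "target_mrna", "treatment", "bio_rep",
                         "tech_rep", "ct"), "wells")
  wells
}
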