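#' Simulate a RIP-qPCR well table
#'
#' Generates Ct values for a bait pull-down and a no-bait (wildtype
#' background) control, each under cycloheximide and puromycin treatment.
#' Cycloheximide preserves the co-translational signal, so the bait's Ct is
#' lowered by `log2(true_fold) / log2(efficiency)` cycles relative to the
#' control; puromycin releases the nascent chain and collapses the true fold
#' to 1. Each biological replicate draws its own mean Ct (Gaussian noise of
#' `ct_sd` cycles); technical replicates scatter around that shared
#' biological mean with the pipetting-scale noise `tech_sd`, which is
#' tighter than the biological spread (same-well repeats of one cDNA).
#'
#' @param true_fold True CHX fold enrichment of the target mRNA over the
#'   no-bait background (>= 0; 1 simulates a null experiment).
#' @param ct_sd Biological-replicate Gaussian noise SD on the Ct scale, in
#'   cycles (>= 0).
#' @param n_bio Number of biological replicates. Fewer than 2 makes the
#'   paired test downstream impossible and triggers a warning.
#' @param n_tech Technical replicates per well group (>= 2).
#' @param tech_sd Technical-replicate noise SD in cycles; defaults to the
#'   smaller of `ct_sd` and 0.1 (technical triplicates of one cDNA are far
#'   tighter than independent cultures).
#' @param base_ct Baseline no-bait Ct (cycles).
#' @param efficiency Amplification efficiency per cycle (2 = perfect
#'   doubling).
#' @param seed Integer seed.
#'
#' @return A tibble of wells with columns `bait` (`"bait"`/`"no-bait"`),
#'   `target_mrna`, `treatment` (`"cycloheximide"`/`"puromycin"`),
#'   `bio_rep`, `tech_rep`, `ct`.
#' @seealso [qpcr_calls()], [call_cotranslational()]
#' @export
sim_qpcr_wells <- function(true_fold = 4,
                           ct_sd = 0.3,
                           n_bio = 5L,
                           n_tech = 3L,
                           tech_sd = min(ct_sd, 0.1),
                           base_ct = 25,
                           efficiency = 2,
                           seed = 1L) {
  check_number(true_fold, "true_fold", lower = 0)
  check_number(ct_sd, "ct_sd", lower = 0)
  check_number(tech_sd, "tech_sd", lower = 0)
  check_number(n_bio, "n_bio", lower = 1, integerish = TRUE)
  check_number(n_tech, "n_tech", lower = 2, integerish = TRUE)
  check_number(efficiency, "efficiency", lower = 1 + 1e-9)
  if (n_bio < 2) {
    warn("n_bio < 2: a paired CHX-vs-puromycin test will not be possible.")
  }

  # Ct shift produced by a given fold at this amplification efficiency
  dct <- function(fold) log2(fold) / log2(efficiency)

  groups <- tidyr::expand_grid(
    bait = c("bait", "no-bait"),
    treatment = c("cycloheximide", "puromycin"),
    bio_rep = seq_len(as.integer(n_bio)))

  with_seed(seed, {
    groups |>
      dplyr::mutate(
        fold = ifelse(.data$bait == "bait" & .data$treatment == "cycloheximide",
                      true_fold, 1),
        bio_mean = base_ct + rnorm(dplyr::n(), 0, ct_sd) - dct(.data$fold)) |>
      tidyr::expand_grid(tech_rep = seq_len(as.integer(n_tech))) |>
      dplyr::mutate(
        target_mrna = "target-mrna",
        ct = .data$bio_mean + rnorm(dplyr::n(), 0, tech_sd)) |>
      dplyr::select("bait", "target_mrna", "treatment", "bio_rep",
                    "tech_rep", "ct")
  })
}
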