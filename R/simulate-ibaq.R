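#' Simulate an iBAQ pull-down intensity table
#'
#' Emulates bait pull-down proteomics quantified by iBAQ: log-normal protein
#' intensities proportional to the bait, a multiplicative batch factor per
#' batch, per-sample scale differences, and known true fold changes applied
#' to chosen protein groups in mutant genotypes. One sample is generated per
#' genotype x batch combination, so every mutant sample has a same-batch
#' wildtype partner.
#'
#' @param n_proteins Number of prey proteins (the bait is added on top).
#' @param genotypes Character vector of genotypes; must contain
#'   `"wildtype"`.
#' @param n_batches Number of batches (one sample per genotype per batch).
#' @param batch_factors Multiplicative factor per batch (recycled).
#' @param sample_scale_sd SD of the per-sample log-normal scale factor
#'   (on the natural-log scale).
#' @param noise_sd SD of the per-measurement log-normal noise
#'   (natural-log scale).
#' @param true_folds Optional tibble `protein`, `genotype`, `fold` giving
#'   true mutant-vs-wildtype fold changes; proteins/genotypes not listed
#'   have fold 1. The bait always has fold 1.
#' @param bait Name of the bait protein (present and positive in every
#'   sample).
#' @param seed Integer seed.
#'
#' @return An `ibaq_sim` list with `ibaq` (long tibble `protein`, `sample`,
#'   `intensity`), `meta` (tibble `sample`, `genotype`, `batch`), `truth`
#'   (the expanded fold table) and `bait`.
#' @seealso [ibaq_foldchange()], [mutant_vs_wt_fold()]
#' @export
sim_ibaq <- function(n_proteins = 20L,
                     genotypes = c("wildtype", "mutant"),
                     n_batches = 4L,
                     batch_factors = 1,
                     sample_scale_sd = 0.1,
                     noise_sd = 0.1,
                     true_folds = NULL,
                     bait = "BAIT",
                     seed = 1L) {
  check_number(n_proteins, "n_proteins", lower = 1, integerish = TRUE)
  check_number(n_batches, "n_batches", lower = 1, integerish = TRUE)
  check_number(sample_scale_sd, "sample_scale_sd", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!"wildtype" %in% genotypes) {
    abort("`genotypes` must include \"wildtype\".")
  }
  if (!is.null(true_folds)) {
    check_columns(true_folds, c("protein", "genotype", "fold"), "true_folds")
    if (bait %in% true_folds$protein) {
      abort("The bait cannot carry a fold change; it is the normalizer.")
    }
  }

  proteins <- c(bait, sprintf("P%03d", seq_len(as.integer(n_proteins))))
  batch_f <- rep_len(batch_factors, n_batches)

  meta <- tidyr::expand_grid(
    genotype = genotypes,
    batch = seq_len(as.integer(n_batches))) |>
    dplyr::mutate(sample = sprintf("%s_b%d", .data$genotype, .data$batch)) |>
    dplyr::select("sample", "genotype", "batch")

  fold_of <- function(protein, genotype) {
    out <- rep(1, length(protein))
    if (!is.null(true_folds)) {
      key <- paste(protein, genotype)
      idx <- match(key, paste(true_folds$protein, true_folds$genotype))
      out[!is.na(idx)] <- true_folds$fold[idx[!is.na(idx)]]
    }
    out
  }

  with_seed(seed, {
    # bait abundant, preys log-normal around 10% of bait
    base <- c(1e7, rlnorm(n_proteins, meanlog = log(1e6), sdlog = 1))
    names(base) <- proteins
    sample_scale <- rlnorm(nrow(meta), 0, sample_scale_sd)

    ibaq <- tidyr::expand_grid(protein = proteins, sample = meta$sample) |>
      dplyr::left_join(meta, by = "sample") |>
      dplyr::mutate(
        intensity = unname(base[.data$protein]) *
          batch_f[.data$batch] *
          sample_scale[match(.data$sample, meta$sample)] *
          fold_of(.data$protein, .data$genotype) *
          rlnorm(dplyr::n(), 0, noise_sd)) |>
      dplyr::select("protein", "sample", "intensity")

    truth <- tidyr::expand_grid(
      protein = proteins,
      genotype = setdiff(genotypes, "wildtype")) |>
      dplyr::mutate(fold = fold_of(.data$protein, .data$genotype))

    structure(list(ibaq = ibaq, meta = meta, truth = truth, bait = bait),
              class = "ibaq_sim")
  })
}
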