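#' Residue window exposed outside the ribosome exit tunnel
#'
#' The ribosome exit tunnel buries roughly the 30-40 most C-terminal
#' residues of the nascent chain, so when the ribosome sits at onset codon
#' `c0` the newly exposed region spans residues
#' `[max(1, c0 - delta_max), max(1, c0 - delta_min)]`.
#'
#' @param onset_codon Onset codon index (vectorised, 1-based, >= 1).
#' @param delta_min,delta_max Exit-tunnel offsets in amino acids
#'   (`0 <= delta_min <= delta_max`).
#' @return A tibble with `exposure_lo` and `exposure_hi` (clipped at 1).
#' @export
exposed_residue_window <- function(onset_codon, delta_min = 30L, delta_max = 40L) {
  check_number(delta_min, "delta_min", lower = 0)
  check_number(delta_max, "delta_max", lower = 0)
  if (delta_min > delta_max) abort("`delta_min` must be <= `delta_max`.")
  if (any(!is.na(onset_codon) & onset_codon < 1)) {
    abort("`onset_codon` must be >= 1.")
  }
  tibble(
    exposure_lo = pmax(1, onset_codon - delta_max),
    exposure_hi = pmax(1, onset_codon - delta_min))
}

# local maximum-likelihood step alignment on pooled IP footprint counts:
# within +/- span codons of the detected onset, place the step where the
# negative-binomial likelihood (plug-in means from the flanking segments,
# method-of-moments overdispersion) is maximal. Detection is not touched;
# this only sharpens the position of an onset the run rule already found.
refine_onset_nb <- function(ip, c0, span, flank) {
  L <- length(ip)
  pre_hi <- c0 - span - 1L
  pre_lo <- max(1L, c0 - span - flank)
  post_lo <- min(L, c0 + span)
  post_hi <- min(L, c0 + span + flank - 1L)
  if (pre_hi - pre_lo < 4L || post_hi - post_lo < 4L) return(c0)
  a <- ip[pre_lo:pre_hi]
  b <- ip[post_lo:post_hi]
  mu1 <- mean(a)
  mu2 <- mean(b)
  if (mu2 <= mu1 || mu1 <= 0) return(c0)
  # average excess-variance estimate of 1/size across the two segments
  phi <- max(((var(a) - mu1) / mu1^2 + (var(b) - mu2) / mu2^2) / 2, 0)
  win <- max(2L, c0 - span):min(L, c0 + span)
  x <- ip[win]
  llr <- if (phi > 0) {
    stats::dnbinom(x, mu = mu2, size = 1 / phi, log = TRUE) -
      stats::dnbinom(x, mu = mu1, size = 1 / phi, log = TRUE)
  } else {
    stats::dpois(x, mu2, log = TRUE) - stats::dpois(x, mu1, log = TRUE)
  }
  s <- rev(cumsum(rev(llr)))   # s[k] = LLR of stepping at win[k]
  win[which.max(s)]            # earliest codon on ties
}

# first start of a run of >= r consecutive TRUEs, or NA
first_run_start <- function(hits, r) {
  if (!length(hits)) return(NA_integer_)
  runs <- rle(hits)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- runs$values & runs$lengths >= r
  if (!any(ok)) NA_integer_ else starts[which(ok)[1L]]
}

call_onset_one <- function(E, theta, min_run, background_frac,
                           background_min) {
  L <- length(E)
  if (L < background_min) {
    inform(sprintf(
      "ORF of %d codons is shorter than the background minimum (%d); using the whole-ORF median as background.",
      L, background_min))
    bg_end <- L
  } else {
    bg_end <- max(floor(L * background_frac), background_min)
  }
  b <- median(E[seq_len(bg_end)])
  thr <- theta * b
  onset <- first_run_start(E >= thr, min_run)
  detected <- !is.na(onset) && mean(E[onset:L]) >= thr
  list(detected = detected,
       onset_codon = if (detected) onset else NA_integer_,
       background = b)
}

#' Call the onset codon of co-translational engagement
#'
#' For each transcript in an enrichment profile, estimates a background
#' enrichment `b` as the median over the 5' quarter of the ORF (at least
#' `background_min` codons; ORFs shorter than that fall back to the
#' whole-ORF median, with a message) and calls the onset as the first codon
#' at which `E(c) >= theta * b` holds for `min_run` consecutive codons. A
#' transcript is `detected` only if such a codon exists and the signal is
#' sustained, i.e. the mean enrichment from the onset to the stop codon is
#' itself `>= theta * b`; this separates true onsets, which stay elevated to
#' the end of the ORF, from transient spikes. If several codons satisfy the
#' run condition the smallest index wins.
#'
#' When the profile carries pooled per-codon IP counts (column `ip_pooled`,
#' produced by [combine_replicates()] and passed through
#' [enrichment_profile()]) and `refine = TRUE`, the position of each
#' detected onset is additionally sharpened by a local negative-binomial
#' step alignment: within `refine_span` codons of the run-rule onset, the
#' step is placed where the count likelihood is maximal, with segment means
#' estimated from `refine_flank`-codon flanks (`refine_passes` passes, each
#' re-centred on the previous). Smoothing blurs the step over the gliding
#' window, so the raw-count alignment recovers codon-level precision that
#' the smoothed threshold crossing alone cannot. Profiles without pooled
#' counts are called by the run rule only.
#'
#' The call is completed with the exposed-residue window implied by the
#' 30-40 amino-acid exit-tunnel offset (see [exposed_residue_window()]).
#'
#' @param profile An [enrichment_profile()] tibble (columns `transcript_id`,
#'   `codon`, `enrichment`), or any tibble with those columns.
#' @param theta Enrichment threshold ratio over background (> 1).
#' @param min_run Required run length in codons (>= 1).
#' @param background_frac Fraction of the ORF (from the 5' end) used as the
#'   background region.
#' @param background_min Minimum background region length in codons.
#' @param refine Sharpen detected onsets on pooled IP counts when available.
#' @param refine_span Search half-width (codons) of the step alignment.
#' @param refine_flank Flank length (codons) used to estimate the pre- and
#'   post-onset count means.
#' @param refine_passes Number of re-centred alignment passes.
#' @param delta_min,delta_max Exit-tunnel offsets passed to
#'   [exposed_residue_window()].
#' @return An `onset_calls` tibble: `transcript_id`, `detected`,
#'   `onset_codon`, `background`, `theta`, `min_run`, `exposure_lo`,
#'   `exposure_hi`.
#' @export
call_onset <- function(profile, theta = 2, min_run = 15L,
                       background_frac = 0.25, background_min = 20L,
                       refine = TRUE, refine_span = 15L, refine_flank = 40L,
                       refine_passes = 3L, delta_min = 30L, delta_max = 40L) {
  check_columns(profile, c("transcript_id", "codon", "enrichment"), "profile")
  check_number(theta, "theta", lower = 1 + 1e-12)
  check_number(min_run, "min_run", lower = 1, integerish = TRUE)

  calls <- profile |>
    dplyr::arrange(.data$transcript_id, .data$codon) |>
    dplyr::reframe(
      as_tibble(call_onset_one(.data$enrichment, theta, min_run,
                               background_frac, background_min)),
      .by = "transcript_id")

  if (refine && "ip_pooled" %in% names(profile)) {
    pooled <- profile |>
      dplyr::arrange(.data$transcript_id, .data$codon) |>
      dplyr::summarise(ip = list(.data$ip_pooled), .by = "transcript_id")
    for (i in which(calls$detected)) {
      ip <- pooled$ip[[match(calls$transcript_id[i], pooled$transcript_id)]]
      c0 <- calls$onset_codon[i]
      for (k in seq_len(refine_passes)) {
        c0 <- refine_onset_nb(ip, c0, refine_span, refine_flank)
      }
      calls$onset_codon[i] <- c0
    }
  }

  exposure <- exposed_residue_window(calls$onset_codon, delta_min, delta_max)
  out <- calls |>
    dplyr::mutate(theta = theta,
                  min_run = as.integer(min_run),
                  exposure_lo = exposure$exposure_lo,
                  exposure_hi = exposure$exposure_hi)
  structure(out, class = c("onset_calls", class(out)))
}

#' Annotate onset calls with overlapping sequence motifs
#'
#' A motif is listed for a call when its residue interval intersects the
#' call's exposed-residue window (closed intervals, 1-based).
#'
#' @param calls An `onset_calls` tibble from [call_onset()].
#' @param motifs Tibble `transcript_id`, `motif_name`, `start_res`,
#'   `end_res` (1-based inclusive residue coordinates).
#' @return `calls` with a `motifs` column (comma-separated motif names;
#'   `""` when none overlap or the transcript was not detected).
#' @export
annotate_motif_overlap <- function(calls, motifs) {
  check_columns(calls, c("transcript_id", "detected",
                         "exposure_lo", "exposure_hi"), "calls")
  check_columns(motifs, c("transcript_id", "motif_name",
                          "start_res", "end_res"), "motifs")
  if (any(motifs$start_res > motifs$end_res)) {
    abort("Motif intervals must have start_res <= end_res.")
  }
  overlaps <- calls |>
    dplyr::select("transcript_id", "exposure_lo", "exposure_hi") |>
    dplyr::inner_join(motifs, by = "transcript_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$start_res <= .data$exposure_hi,
                  .data$end_res >= .data$exposure_lo) |>
    dplyr::summarise(motifs = paste(.data$motif_name, collapse = ","),
                     .by = "transcript_id")
  out <- calls |>
    dplyr::left_join(overlaps, by = "transcript_id") |>
    dplyr::mutate(motifs = dplyr::if_else(.data$detected,
                                          dplyr::coalesce(.data$motifs, ""),
                                          ""))
  structure(out, class = unique(c("onset_calls", class(out))))
}
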