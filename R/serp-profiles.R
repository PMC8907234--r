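#' Read per-position footprint counts and collapse them to codons
#'
#' Reads a three-column TSV (`transcript_id`, `pos_nt`, `count`; nucleotide
#' positions 1-based within the ORF) and collapses nucleotide positions to
#' codons via `codon = floor((pos - 1) / 3) + 1` after applying the
#' configured P-site offset. Positions falling outside the annotated ORF are
#' dropped and their number reported. Codons with no reads are zero-filled so
#' every track spans the full ORF.
#'
#' @param path Path to the counts TSV.
#' @param annotation Tibble with `transcript_id` and `length_codons` (e.g.
#'   from [read_annotation()]).
#' @param condition Library condition, `"IP"` or `"total"`.
#' @param replicate Replicate index of this library.
#' @param psite_offset P-site offset in nucleotides added to each 5'-end
#'   position before codon assignment (default 0: positions are taken as
#'   already P-site-assigned).
#' @param library_size Total mapped footprints in the library; defaults to
#'   the sum of the counts in the file.
#'
#' @return A footprint-track tibble: `transcript_id`, `condition`,
#'   `replicate`, `codon`, `count`, `library_size`.
#' @export
read_position_counts <- function(path, annotation,
                                 condition = c("IP", "total"),
                                 replicate = 1L,
                                 psite_offset = 0L,
                                 library_size = NULL) {
  condition <- match.arg(condition)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  codon_counts(raw, annotation, condition = condition, replicate = replicate,
               psite_offset = psite_offset, library_size = library_size)
}

#' Collapse nucleotide-level counts to a per-codon footprint track
#'
#' @param counts Tibble with `transcript_id`, `pos_nt`, `count`.
#' @inheritParams read_position_counts
#' @return A footprint-track tibble (see [read_position_counts()]).
#' @export
codon_counts <- function(counts, annotation,
                         condition = c("IP", "total"),
                         replicate = 1L,
                         psite_offset = 0L,
                         library_size = NULL) {
  condition <- match.arg(condition)
  check_columns(counts, c("transcript_id", "pos_nt", "count"), "counts")
  check_columns(annotation, c("transcript_id", "length_codons"), "annotation")
  bad_rows <- which(!is.finite(counts$pos_nt) | !is.finite(counts$count) |
                      counts$count < 0 | counts$pos_nt %% 1 != 0)
  if (length(bad_rows)) {
    abort(sprintf("Malformed count rows (non-integer position or negative count) at line(s): %s.",
                  paste(head(bad_rows, 10L), collapse = ", ")))
  }
  unknown <- setdiff(unique(counts$transcript_id), annotation$transcript_id)
  if (length(unknown)) {
    abort(sprintf("Transcript(s) absent from annotation: %s.",
                  paste(unknown, collapse = ", ")))
  }

  lib <- library_size %||% sum(counts$count)
  if (lib <= 0) abort("Library size must be positive.")

  assigned <- counts |>
    dplyr::left_join(annotation, by = "transcript_id") |>
    dplyr::mutate(codon = (.data$pos_nt + psite_offset - 1) %/% 3 + 1)
  outside <- assigned$codon < 1 | assigned$codon > assigned$length_codons
  if (any(outside)) {
    inform(sprintf("Dropped %d position(s) outside annotated ORFs (%s reads).",
                   sum(outside), sum(assigned$count[outside])))
  }

  kept <- assigned[!outside, , drop = FALSE] |>
    dplyr::group_by(.data$transcript_id, .data$codon) |>
    dplyr::summarise(count = as.integer(sum(.data$count)), .groups = "drop")

  # zero-filled codon grid over the transcripts present in the input
  full <- annotation |>
    dplyr::filter(.data$transcript_id %in% counts$transcript_id)
  full <- tibble(
    transcript_id = rep(full$transcript_id, full$length_codons),
    codon = unlist(lapply(full$length_codons, seq_len)))

  full |>
    dplyr::left_join(kept, by = c("transcript_id", "codon")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      condition = condition,
      replicate = as.integer(replicate),
      library_size = lib) |>
    dplyr::select("transcript_id", "condition", "replicate", "codon",
                  "count", "library_size")
}

#' Scale footprint counts to reads per million
#'
#' Adds a `density` column: `count * 1e6 / library_size`.
#'
#' @param tracks Footprint-track tibble with `count` and `library_size`.
#' @return The input with a `density` column (RPM).
#' @export
normalize_rpm <- function(tracks) {
  check_columns(tracks, c("count", "library_size"), "tracks")
  if (any(tracks$library_size <= 0)) {
    abort("All library sizes must be positive.")
  }
  dplyr::mutate(tracks, density = .data$count * 1e6 / .data$library_size)
}

#' Combine replicate tracks into one density track per condition
#'
#' Replicates are combined by averaging their RPM densities per codon
#' (default), or by pooling raw counts and rescaling by the pooled library
#' size.
#'
#' @param tracks Footprint-track tibble covering one or more replicates.
#' @param method `"mean_rpm"` (mean of per-replicate RPM densities) or
#'   `"pooled"` (sum counts, then RPM with the summed library size).
#' @return Tibble `transcript_id`, `condition`, `codon`, `density`,
#'   `n_replicates`.
#' @export
combine_replicates <- function(tracks, method = c("mean_rpm", "pooled")) {
  method <- match.arg(method)
  check_columns(tracks, c("transcript_id", "condition", "replicate",
                          "codon", "count", "library_size"), "tracks")
  lens <- tracks |>
    dplyr::summarise(len = max(.data$codon),
                     n = dplyr::n(),
                     .by = c("transcript_id", "condition", "replicate"))
  mismatch <- lens |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$len) == 1 &&
                       dplyr::n_distinct(.data$n) == 1,
                     .by = c("transcript_id", "condition"))
  if (!all(mismatch$ok)) {
    abort(sprintf("Replicate tracks differ in length for: %s.",
                  paste(mismatch$transcript_id[!mismatch$ok], collapse = ", ")))
  }

  if (method == "mean_rpm") {
    tracks |>
      normalize_rpm() |>
      dplyr::summarise(density = mean(.data$density),
                       pooled_count = sum(.data$count),
                       n_replicates = dplyr::n(),
                       .by = c("transcript_id", "condition", "codon"))
  } else {
    tracks |>
      dplyr::summarise(pooled_count = sum(.data$count),
                       library_size = sum(.data$library_size),
                       n_replicates = dplyr::n(),
                       .by = c("transcript_id", "condition", "codon")) |>
      dplyr::mutate(density = .data$pooled_count * 1e6 / .data$library_size) |>
      dplyr::select("transcript_id", "condition", "codon", "density",
                    "pooled_count", "n_replicates")
  }
}

#' Gliding (centred moving) average with truncated edges
#'
#' Centred moving mean of window `w`; at the edges the window truncates to
#' the positions available, so the output has the same length as the input.
#'
#' @param values Numeric vector.
#' @param w Odd window width >= 1.
#' @return Numeric vector of smoothed values, same length as `values`.
#' @export
gliding_average <- function(values, w) {
  check_number(w, "w", lower = 1, integerish = TRUE)
  if (w %% 2 == 0) abort("`w` must be odd.")
  n <- length(values)
  if (n == 0L || w == 1L) return(values)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smoothed per-codon IP/total enrichment profile
#'
#' Computes the SeRP enrichment `E(c) = (smooth(IP density) + alpha) /
#' (smooth(total density) + alpha)` per codon, smoothing each combined
#' density track with a gliding average of window `window` before taking the
#' ratio. The pseudocount `alpha` (in RPM) keeps the ratio finite where the
#' total density is zero.
#'
#' @param combined Combined density tibble from [combine_replicates()],
#'   containing both `"IP"` and `"total"` conditions.
#' @param window Odd gliding-average window in codons.
#' @param pseudocount Pseudocount alpha >= 0, in RPM.
#' @return An `enrichment_profile` tibble: `transcript_id`, `codon`,
#'   `ip_density`, `total_density`, `ip_smooth`, `total_smooth`,
#'   `enrichment`; window, pseudocount and replicate counts are carried as
#'   attributes (`window`, `pseudocount`, `n_ip_reps`, `n_total_reps`).
#' @export
enrichment_profile <- function(combined, window = 15L, pseudocount = 0.5) {
  check_columns(combined, c("transcript_id", "condition", "codon", "density"),
                "combined")
  check_number(pseudocount, "pseudocount", lower = 0)
  missing_cond <- setdiff(c("IP", "total"), unique(combined$condition))
  if (length(missing_cond)) {
    abort(sprintf("`combined` lacks condition(s): %s.",
                  paste(missing_cond, collapse = ", ")))
  }

  nreps <- function(cond) {
    if ("n_replicates" %in% names(combined)) {
      max(combined$n_replicates[combined$condition == cond])
    } else {
      NA_integer_
    }
  }

  keep_cols <- intersect(c("transcript_id", "condition", "codon", "density",
                           "pooled_count"), names(combined))
  wide <- combined |>
    dplyr::select(dplyr::all_of(keep_cols)) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = dplyr::any_of(c("density",
                                                     "pooled_count"))) |>
    dplyr::arrange(.data$transcript_id, .data$codon)
  if ("density_IP" %in% names(wide)) {
    wide <- dplyr::rename(wide, IP = "density_IP", total = "density_total")
  }
  if (anyNA(wide$IP) || anyNA(wide$total)) {
    abort("IP and total tracks must cover the same codons per transcript.")
  }

  out <- wide |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(
      ip_smooth = gliding_average(.data$IP, window),
      total_smooth = gliding_average(.data$total, window)) |>
    dplyr::ungroup()
  if (pseudocount == 0 && any(out$total_smooth == 0)) {
    abort("Zero total density with pseudocount 0; use a positive pseudocount.")
  }
  out <- out |>
    dplyr::mutate(
      enrichment = (.data$ip_smooth + pseudocount) /
        (.data$total_smooth + pseudocount)) |>
    dplyr::rename(ip_density = "IP", total_density = "total")
  if ("pooled_count_IP" %in% names(out)) {
    out <- dplyr::rename(out, ip_pooled = "pooled_count_IP",
                         total_pooled = "pooled_count_total")
  }
  out <- out |>
    dplyr::select("transcript_id", "codon", "ip_density", "total_density",
                  "ip_smooth", "total_smooth", "enrichment",
                  dplyr::any_of(c("ip_pooled", "total_pooled")))

  structure(out,
            class = c("enrichment_profile", class(out)),
            window = as.integer(window),
            pseudocount = pseudocount,
            n_ip_reps = nreps("IP"),
            n_total_reps = nreps("total"))
}

#' One-call SeRP enrichment pipeline
#'
#' Convenience wrapper: RPM normalization, replicate combination and
#' smoothed enrichment, i.e. `tracks |> combine_replicates() |>
#' enrichment_profile()`.
#'
#' @inheritParams combine_replicates
#' @inheritParams enrichment_profile
#' @param tracks Footprint-track tibble (e.g. `sim_footprints(spec)$tracks`
#'   or stacked [read_position_counts()] outputs).
#' @return An `enrichment_profile` tibble.
#' @export
serp_enrichment <- function(tracks, window = 15L, pseudocount = 0.5,
                            method = c("mean_rpm", "pooled")) {
  tracks |>
    combine_replicates(method = method) |>
    enrichment_profile(window = window, pseudocount = pseudocount)
}
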