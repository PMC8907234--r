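#' Specification of a synthetic SeRP experiment
#'
#' Bundles the parameters of a simulated selective-ribosome-profiling (SeRP)
#' experiment: a set of ORFs, the codon at which the bait starts to engage the
#' nascent chain (the onset), the IP-over-total enrichment fold from that
#' codon onward, sequencing depth, negative-binomial overdispersion, and the
#' number of biological replicates per library.
#'
#' Counts are drawn per codon as NB with mean `mean_depth` (total libraries,
#' and IP libraries before the onset) or `mean_depth * enrichment_fold` (IP
#' libraries from the onset codon onward). `nb_dispersion` is the NB size
#' parameter, so `var = mu + mu^2 / nb_dispersion`; the Poisson limit is
#' recovered as `nb_dispersion -> Inf`. An optional `ramp_width` replaces the
#' hard step in the IP mean by a linear ramp spanning that many codons, for
#' robustness checks of the onset caller.
#'
#' @param n_transcripts Number of ORFs to simulate.
#' @param orf_length ORF length(s) in codons (recycled; each must be >= 10).
#' @param onset_codon Onset codon per transcript (recycled). `NA` means the
#'   bait never engages that transcript (a null transcript).
#' @param enrichment_fold IP/total enrichment fold from the onset onward
#'   (>= 1; 1 gives a null experiment).
#' @param mean_depth Mean footprint count per codon per replicate.
#' @param nb_dispersion Negative-binomial size parameter (> 0); `Inf` draws
#'   Poisson counts.
#' @param n_replicates Biological replicates per library (IP and total).
#' @param ramp_width Width in codons of a linear enrichment ramp at the onset
#'   (0 = hard step).
#'
#' @return A `serp_sim_spec` object (a validated list).
#' @seealso [sim_footprints()], [sim_annotation()]
#' @export
serp_sim_spec <- function(n_transcripts = 1L,
                          orf_length = 300L,
                          onset_codon = NA_integer_,
                          enrichment_fold = 4,
                          mean_depth = 5,
                          nb_dispersion = 0.3,
                          n_replicates = 4L,
                          ramp_width = 0L) {
  check_number(n_transcripts, "n_transcripts", lower = 1, integerish = TRUE)
  check_number(enrichment_fold, "enrichment_fold", lower = 1)
  check_number(mean_depth, "mean_depth", lower = 0)
  check_number(nb_dispersion, "nb_dispersion", lower = 1e-12)
  check_number(n_replicates, "n_replicates", lower = 1, integerish = TRUE)
  check_number(ramp_width, "ramp_width", lower = 0, integerish = TRUE)

  n <- as.integer(n_transcripts)
  len <- rep_len(as.integer(orf_length), n)
  if (any(is.na(len)) || any(len < 10L)) {
    abort("All `orf_length` values must be >= 10 codons.")
  }
  onset <- rep_len(as.integer(onset_codon), n)
  bad <- !is.na(onset) & (onset < 1L | onset >= len)
  if (any(bad)) {
    abort(sprintf(
      "`onset_codon` must lie in [1, orf_length) when present (offending transcripts: %s).",
      paste(which(bad), collapse = ", ")))
  }

  structure(
    list(n_transcripts = n, orf_length = len, onset_codon = onset,
         enrichment_fold = enrichment_fold, mean_depth = mean_depth,
         nb_dispersion = nb_dispersion,
         n_replicates = as.integer(n_replicates),
         ramp_width = as.integer(ramp_width)),
    class = "serp_sim_spec")
}

#' @export
print.serp_sim_spec <- function(x, ...) {
  cat(sprintf(
    "<serp_sim_spec> %d transcript(s), %d replicate(s)/library, depth %g, fold %g, NB size %g\n",
    x$n_transcripts, x$n_replicates, x$mean_depth, x$enrichment_fold,
    x$nb_dispersion))
  invisible(x)
}

transcript_ids <- function(n) sprintf("TX%04d", seq_len(n))

#' Simulate a toy ORF annotation with coding sequences
#'
#' Builds one single-exon ORF per transcript (1-based, inclusive coordinates,
#' spanning `3 * orf_length` nucleotides) together with random coding
#' sequences that begin with ATG and end with a TAA stop. The result can be
#' written to GFF3/FASTA with [write_annotation()].
#'
#' @param spec A [serp_sim_spec()].
#' @param seed Integer seed; the same spec and seed reproduce the annotation
#'   byte-identically.
#'
#' @return An `orf_annotation`: a list with `features` (tibble of
#'   `transcript_id`, `start`, `end`, `length_codons`) and `sequences`
#'   (named character vector of nucleotide sequences).
#' @export
sim_annotation <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "serp_sim_spec"))
  ids <- transcript_ids(spec$n_transcripts)
  seqs <- with_seed(seed, {
    vapply(spec$orf_length, function(len) {
      body <- sample(c("A", "C", "G", "T"), 3L * (len - 2L), replace = TRUE)
      paste0("ATG", paste(body, collapse = ""), "TAA")
    }, character(1))
  })
  names(seqs) <- ids
  features <- tibble(
    transcript_id = ids,
    start = 1L,
    end = 3L * spec$orf_length,
    length_codons = spec$orf_length)
  structure(list(features = features, sequences = seqs),
            class = "orf_annotation")
}

#' Write a toy ORF annotation to GFF3 and FASTA
#'
#' @param annotation An `orf_annotation` from [sim_annotation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the written `annotation.gff3` and
#'   `sequences.fa`.
#' @export
write_annotation <- function(annotation, dir) {
  stopifnot(inherits(annotation, "orf_annotation"))
  for (pkg in c("rtracklayer", "GenomicRanges", "Biostrings")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(sprintf("Package '%s' is required to write annotation files.", pkg))
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ft <- annotation$features
  gr <- GenomicRanges::GRanges(
    seqnames = ft$transcript_id,
    ranges = IRanges::IRanges(start = ft$start, end = ft$end),
    strand = "+",
    type = "CDS",
    phase = 0L,
    ID = ft$transcript_id)
  gff <- file.path(dir, "annotation.gff3")
  fa <- file.path(dir, "sequences.fa")
  rtracklayer::export(gr, gff, format = "gff3")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(annotation$sequences), fa)
  invisible(c(gff = gff, fasta = fa))
}

#' Read an ORF annotation from GFF3
#'
#' Reads CDS/ORF features and derives per-transcript lengths in codons.
#'
#' @param path Path to a GFF3 file as written by [write_annotation()] (one
#'   feature per transcript, 1-based inclusive coordinates).
#' @return A tibble with `transcript_id` and `length_codons`.
#' @export
read_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Package 'rtracklayer' is required to read GFF3 annotation.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    length_codons = as.integer(BiocGenerics::width(gr) %/% 3L))
}

nb_draw <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, lambda = mu) else rnbinom(n, mu = mu, size = size)
}

# per-codon IP mean: baseline before onset, fold * baseline from onset on,
# with an optional linear ramp of `ramp` codons centred at the step
ip_mean_profile <- function(len, onset, depth, fold, ramp) {
  mu <- rep(depth, len)
  if (is.na(onset)) return(mu)
  if (ramp <= 0L) {
    mu[onset:len] <- depth * fold
  } else {
    half <- ramp / 2
    frac <- pmin(1, pmax(0, (seq_len(len) - (onset - half)) / ramp))
    mu <- depth * (1 + (fold - 1) * frac)
  }
  mu
}

#' Simulate SeRP footprint tracks
#'
#' Draws per-codon footprint counts for the total-translatome and IP
#' libraries of every replicate. Total counts are NB around `mean_depth`
#' everywhere; IP counts switch from `mean_depth` to
#' `mean_depth * enrichment_fold` at each transcript's onset codon. The
#' library size of each (condition, replicate) library is the sum of its
#' counts across transcripts.
#'
#' @param spec A [serp_sim_spec()].
#' @param seed Integer seed (same spec + seed gives identical output).
#'
#' @return A `serp_sim` list with
#'   * `tracks`: tibble `transcript_id`, `condition` (`"IP"`/`"total"`),
#'     `replicate`, `codon`, `count`, `library_size`;
#'   * `truth`: tibble `transcript_id`, `length_codons`, `onset_codon`,
#'     `enrichment_fold` recording the simulated ground truth.
#' @export
sim_footprints <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "serp_sim_spec"))
  ids <- transcript_ids(spec$n_transcripts)
  lens <- spec$orf_length

  grid <- tidyr::expand_grid(
    condition = c("total", "IP"),
    replicate = seq_len(spec$n_replicates))

  tracks <- with_seed(seed, {
    purrr::pmap_dfr(grid, function(condition, replicate) {
      counts <- purrr::map2(lens, spec$onset_codon, function(len, onset) {
        mu <- if (condition == "IP") {
          ip_mean_profile(len, onset, spec$mean_depth, spec$enrichment_fold,
                          spec$ramp_width)
        } else {
          rep(spec$mean_depth, len)
        }
        nb_draw(len, mu, spec$nb_dispersion)
      })
      tibble(
        transcript_id = rep(ids, lens),
        condition = condition,
        replicate = as.integer(replicate),
        codon = unlist(lapply(lens, seq_len)),
        count = as.integer(unlist(counts)))
    })
  })

  tracks <- tracks |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::mutate(library_size = sum(.data$count)) |>
    dplyr::ungroup()

  truth <- tibble(
    transcript_id = ids,
    length_codons = lens,
    onset_codon = spec$onset_codon,
    enrichment_fold = ifelse(is.na(spec$onset_codon), 1, spec$enrichment_fold))

  structure(list(tracks = tracks, truth = truth, spec = spec),
            class = "serp_sim")
}
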