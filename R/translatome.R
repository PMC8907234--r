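#' Per-gene log2 total enrichment (TE) per replicate pair
#'
#' TE contrasts a gene's footprint share in the IP library against its share
#' in the total-translatome library:
#' `TE = log2((ip + alpha) / N_ip) - log2((total + alpha) / N_total)`,
#' where `N` are library sizes and `alpha` a pseudocount that keeps the logs
#' finite for zero-count genes. Replicates are paired by replicate index;
#' replicates present in only one condition are dropped with a message, as
#' are genes missing from a library.
#'
#' @param counts Long tibble of per-ORF footprint counts: `gene`, `sample`,
#'   `count`.
#' @param meta Sample metadata tibble: `sample`, `condition`
#'   (`"IP"`/`"total"`), `replicate`.
#' @param pseudocount Pseudocount alpha added to each count (default 0.5).
#' @param lib_sizes Optional tibble `sample`, `library_size`; defaults to
#'   per-sample count sums.
#' @return Tibble `gene`, `replicate`, `te` (log2 scale).
#' @export
total_enrichment <- function(counts, meta, pseudocount = 0.5,
                             lib_sizes = NULL) {
  check_columns(counts, c("gene", "sample", "count"), "counts")
  check_columns(meta, c("sample", "condition", "replicate"), "meta")
  check_number(pseudocount, "pseudocount", lower = 0)
  if (!all(meta$condition %in% c("IP", "total"))) {
    abort("`meta$condition` must be \"IP\" or \"total\".")
  }

  if (is.null(lib_sizes)) {
    lib_sizes <- counts |>
      dplyr::summarise(library_size = sum(.data$count), .by = "sample")
  }
  check_columns(lib_sizes, c("sample", "library_size"), "lib_sizes")
  if (any(lib_sizes$library_size <= 0)) {
    abort("All library sizes must be positive.")
  }

  long <- counts |>
    dplyr::inner_join(meta, by = "sample") |>
    dplyr::inner_join(lib_sizes, by = "sample") |>
    dplyr::mutate(
      log_prop = log2((.data$count + pseudocount) / .data$library_size))

  wide <- long |>
    dplyr::select("gene", "condition", "replicate", "log_prop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "log_prop")
  if (!all(c("IP", "total") %in% names(wide))) {
    abort("Counts must include both IP and total samples.")
  }
  unpaired <- is.na(wide$IP) | is.na(wide$total)
  if (any(unpaired)) {
    inform(sprintf(
      "Dropped %d gene x replicate combination(s) missing one condition.",
      sum(unpaired)))
  }
  wide |>
    dplyr::filter(!unpaired) |>
    dplyr::mutate(te = .data$IP - .data$total) |>
    dplyr::select("gene", "replicate", "te")
}

# invert the trigamma function by Newton iteration (solves trigamma(x) = y)
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderated t-test on TE values
#'
#' Fits, per gene, the one-coefficient model `TE ~ 1` and moderates the
#' residual variances across genes in the empirical-Bayes fashion of the
#' moderated t-statistic: the per-gene sample variances `s^2` (df `d = n-1`)
#' are assumed to follow a scaled F prior with hyperparameters `(d0, s0^2)`
#' estimated by method of moments on `log s^2`; the posterior variance
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` then yields
#' `t = beta / (s~ / sqrt(n))` on `d0 + d` degrees of freedom. P-values are
#' two-sided and adjusted with [bh_adjust()].
#'
#' @param te TE values: either the long tibble from [total_enrichment()]
#'   (`gene`, `te`) or a numeric matrix with genes as rows.
#' @param prior_df Optional forced prior df `d0`: `0` recovers the ordinary
#'   one-sample t-test, `Inf` fully shrinks all variances to `s0^2`;
#'   `NULL` (default) estimates `d0` from the data.
#' @param var_floor Floor applied to zero sample variances (flagged with a
#'   message).
#' @return A `moderated_fit` object; see [tidy.moderated_fit()] for the
#'   per-gene table and [glance.moderated_fit()] for the hyperparameters.
#' @export
fit_moderated <- function(te, prior_df = NULL, var_floor = 1e-12) {
  if (is.matrix(te)) {
    te <- tibble(
      gene = rep(rownames(te) %||% paste0("g", seq_len(nrow(te))),
                 times = ncol(te)),
      te = as.vector(te))
    te <- te[!is.na(te$te), , drop = FALSE]
  }
  check_columns(te, c("gene", "te"), "te")

  per_gene <- te |>
    dplyr::summarise(n = dplyr::n(),
                     beta = mean(.data$te),
                     s2 = var(.data$te),
                     .by = "gene")
  dropped <- per_gene$n < 2
  if (any(dropped)) {
    inform(sprintf("Dropped %d gene(s) with fewer than 2 TE replicates.",
                   sum(dropped)))
    per_gene <- per_gene[!dropped, , drop = FALSE]
  }
  if (!nrow(per_gene)) abort("No gene has >= 2 TE replicates.")
  zero_var <- per_gene$s2 < var_floor
  if (any(zero_var)) {
    inform(sprintf("Floored %d zero residual variance(s) at %g.",
                   sum(zero_var), var_floor))
    per_gene$s2[zero_var] <- var_floor
  }
  per_gene$d <- per_gene$n - 1L

  # method-of-moments fit of the scaled-F prior on log s^2
  e <- log(per_gene$s2) - digamma(per_gene$d / 2) + log(per_gene$d / 2)
  emean <- mean(e)
  if (nrow(per_gene) > 1) {
    evar <- var(e) - mean(trigamma(per_gene$d / 2))
  } else {
    evar <- 0
  }
  if (is.finite(evar) && evar > 0) {
    d0_hat <- 2 * trigamma_inverse(evar)
    s0_hat <- exp(emean + digamma(d0_hat / 2) - log(d0_hat / 2))
  } else {
    d0_hat <- Inf
    s0_hat <- exp(emean)
  }
  d0 <- prior_df %||% d0_hat
  check_number(d0, "prior_df", lower = 0)
  s0 <- s0_hat

  post_var <- if (is.infinite(d0)) {
    rep(s0, nrow(per_gene))
  } else {
    (d0 * s0 + per_gene$d * per_gene$s2) / (d0 + per_gene$d)
  }
  df_total <- d0 + per_gene$d
  t_stat <- per_gene$beta / sqrt(post_var / per_gene$n)
  p <- if (all(is.infinite(df_total))) {
    2 * stats::pnorm(-abs(t_stat))
  } else {
    2 * pt(-abs(t_stat), df = df_total)
  }

  table <- tibble(
    gene = per_gene$gene,
    n = per_gene$n,
    log2_te = per_gene$beta,
    s2 = per_gene$s2,
    df = per_gene$d,
    t = t_stat,
    p_value = p,
    q_value = bh_adjust(p))

  structure(list(table = table, prior_df = d0, prior_var = s0,
                 estimated_prior_df = d0_hat, var_floor = var_floor),
            class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> %d genes; prior df %.4g, prior variance %.4g\n",
              nrow(x$table), x$prior_df, x$prior_var))
  print(head(x$table))
  invisible(x)
}

#' Tidy a moderated fit into its per-gene result table
#'
#' @param x A `moderated_fit` from [fit_moderated()].
#' @param ... Unused.
#' @return Tibble `gene`, `n`, `log2_te`, `s2`, `df`, `t`, `p_value`,
#'   `q_value`.
#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' One-row summary of a moderated fit's hyperparameters
#'
#' @param x A `moderated_fit` from [fit_moderated()].
#' @param ... Unused.
#' @return Tibble `n_genes`, `prior_df`, `prior_var`,
#'   `n_significant` (genes with `q_value < 0.05`).
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    prior_df = x$prior_df,
    prior_var = x$prior_var,
    n_significant = sum(x$table$q_value < 0.05))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)` with the original order
#' restored.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("`pvalues` must be numeric.")
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Co-translational event density
#'
#' Number of co-translational events divided by the number of proteins in
#' the group. Collective or secondary bindings are expected to be collapsed
#' to a single event by the caller before counting.
#'
#' @param n_events Number of events (vectorised, >= 0).
#' @param n_proteins Number of proteins per group (> 0).
#' @return `n_events / n_proteins`.
#' @export
event_density <- function(n_events, n_proteins) {
  if (any(n_proteins <= 0)) abort("`n_proteins` must be positive.")
  if (any(n_events < 0)) abort("`n_events` must be non-negative.")
  n_events / n_proteins
}
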