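#' Define a protein-complex assembly pathway
#'
#' An assembly pathway is a binary tree over `n` subunit leaves with `n - 1`
#' pairwise joins, each join competing against non-specific binding and each
#' unassembled part (subunit or intermediate) exposed to an orphan hazard
#' while it waits for its partner. The model has four failure/rescue
#' ingredients:
#'
#' * `s`: probability that a join is the specific one rather than a
#'   promiscuous capture (specificity of the specific-vs-nonspecific
#'   binding competition);
#' * `lambda`: hazard rate per unit time of an orphan part being lost to
#'   misassembly or aggregation while it waits;
#' * `tau`: waiting time per join for a diffusive encounter;
#'   `tau_tr` replaces it for co-translational joins, whose encounter is
#'   limited by translation speed rather than diffusion of dilute species;
#' * `delta >= 1`: dwell-time factor of co-translational capture, which
#'   multiplies the specific binding odds, giving the effective
#'   specificity `s_eff = s * delta / (s * delta + (1 - s))`.
#'
#' Joins are scheduled level-synchronously: a join fires one wait after the
#' later of its two inputs becomes available, so a leaf is available at
#' time 0 and an intermediate at its own join time. For a co-translational
#' join the nascent-chain leaf (the right child when both children are
#' leaves, otherwise the leaf child) is captured on the ribosome and
#' accrues no orphan exposure.
#'
#' @param tree Either an integer `n >= 1` (interpreted via `topology`) or a
#'   nested list of character leaf names describing a binary tree, e.g.
#'   `list(list("A", "B"), list("C", "D"))`.
#' @param s Per-join specificity in (0, 1].
#' @param lambda Orphan hazard rate (>= 0) per unit time.
#' @param tau Waiting time per diffusive join (>= 0).
#' @param tau_tr Waiting time per co-translational join (default `tau`).
#' @param cotranslational Join indices flagged as co-translational (joins
#'   are numbered in post-order: left subtree, right subtree, then the
#'   node), or `TRUE` for all joins.
#' @param delta Dwell-time factor (>= 1) of co-translational capture.
#' @param topology `"sequential"` (a chain: each new subunit joins the
#'   growing complex) or `"balanced"` (recursive halving), used when `tree`
#'   is given as a subunit count.
#' @return An `assembly_pathway` object.
#' @seealso [closed_form_yield()], [simulate_assembly()], [yield_vs_n()]
#' @export
assembly_pathway <- function(tree, s = 0.9, lambda = 0.1, tau = 1,
                             tau_tr = tau, cotranslational = integer(0),
                             delta = 1,
                             topology = c("sequential", "balanced")) {
  topology <- match.arg(topology)
  check_number(s, "s", lower = 1e-12, upper = 1)
  check_number(lambda, "lambda", lower = 0)
  check_number(tau, "tau", lower = 0)
  check_number(tau_tr, "tau_tr", lower = 0)
  check_number(delta, "delta", lower = 1)

  if (is.numeric(tree) && length(tree) == 1L) {
    tree <- build_topology(as.integer(tree), topology)
  }
  nodes <- parse_tree(tree)
  n_joins <- sum(!nodes$is_leaf)
  if (isTRUE(cotranslational)) cotranslational <- seq_len(n_joins)
  cotranslational <- as.integer(cotranslational)
  if (any(cotranslational < 1 | cotranslational > max(n_joins, 1L))) {
    abort(sprintf("`cotranslational` join indices must lie in [1, %d].",
                  n_joins))
  }

  structure(
    list(nodes = nodes, s = s, lambda = lambda, tau = tau, tau_tr = tau_tr,
         cotranslational = cotranslational, delta = delta),
    class = "assembly_pathway")
}

#' @rdname assembly_pathway
#' @param n Number of subunit leaves.
#' @param ... Passed on to [assembly_pathway()].
#' @export
sequential_pathway <- function(n, ...) {
  assembly_pathway(n, topology = "sequential", ...)
}

#' @rdname assembly_pathway
#' @export
balanced_pathway <- function(n, ...) {
  assembly_pathway(n, topology = "balanced", ...)
}

build_topology <- function(n, topology) {
  check_number(n, "n", lower = 1, integerish = TRUE)
  leaves <- sprintf("S%d", seq_len(n))
  if (n == 1L) return(leaves[[1L]])
  if (topology == "sequential") {
    tree <- leaves[[1L]]
    for (i in 2:n) tree <- list(tree, leaves[[i]])
    tree
  } else {
    split_balanced <- function(v) {
      if (length(v) == 1L) return(v[[1L]])
      k <- ceiling(length(v) / 2)
      list(split_balanced(v[seq_len(k)]), split_balanced(v[-seq_len(k)]))
    }
    split_balanced(leaves)
  }
}

# flatten a nested binary tree into a post-order node table;
# children of node i are given as node indices (0 for none)
parse_tree <- function(tree) {
  rows <- list()
  walk <- function(node) {
    if (!is.list(node)) {
      if (!is.character(node) || length(node) != 1L) {
        abort("Tree leaves must be single character names.")
      }
      rows[[length(rows) + 1L]] <<- list(label = node, left = 0L, right = 0L,
                                         is_leaf = TRUE)
      return(length(rows))
    }
    if (length(node) != 2L) {
      abort("Every internal tree node must have exactly two children.")
    }
    l <- walk(node[[1L]])
    r <- walk(node[[2L]])
    rows[[length(rows) + 1L]] <<- list(label = NA_character_, left = l,
                                       right = r, is_leaf = FALSE)
    length(rows)
  }
  walk(tree)
  nodes <- dplyr::bind_rows(lapply(rows, as_tibble))
  n_leaves <- sum(nodes$is_leaf)
  labs <- nodes$label[nodes$is_leaf]
  if (anyDuplicated(labs)) abort("Leaf names must be unique.")
  if (sum(!nodes$is_leaf) != n_leaves - 1L && n_leaves > 1L) {
    abort("A binary tree over n leaves must have exactly n - 1 joins.")
  }
  nodes$join_id <- NA_integer_
  nodes$join_id[!nodes$is_leaf] <- seq_len(sum(!nodes$is_leaf))
  nodes$label[!nodes$is_leaf] <- sprintf("join%d",
                                         nodes$join_id[!nodes$is_leaf])
  nodes
}

#' @export
print.assembly_pathway <- function(x, ...) {
  n <- sum(x$nodes$is_leaf)
  cat(sprintf(
    "<assembly_pathway> %d subunits, %d joins (%d co-translational); s = %g, lambda = %g, tau = %g, tau_tr = %g, delta = %g\n",
    n, sum(!x$nodes$is_leaf), length(x$cotranslational), x$s, x$lambda,
    x$tau, x$tau_tr, x$delta))
  invisible(x)
}

effective_specificity <- function(s, delta) s * delta / (s * delta + (1 - s))

# deterministic level-synchronous schedule: per-node ready times and
# per-part exposures (a part = any node except the finished root product)
pathway_schedule <- function(pathway) {
  nodes <- pathway$nodes
  n_nodes <- nrow(nodes)
  cot <- !nodes$is_leaf & nodes$join_id %in% pathway$cotranslational
  wait <- ifelse(cot, pathway$tau_tr, pathway$tau)

  ready <- numeric(n_nodes)
  for (i in seq_len(n_nodes)) {      # post-order: children precede parents
    if (!nodes$is_leaf[i]) {
      ready[i] <- max(ready[nodes$left[i]], ready[nodes$right[i]]) + wait[i]
    }
  }

  parent <- integer(n_nodes)
  for (i in seq_len(n_nodes)) {
    if (!nodes$is_leaf[i]) {
      parent[nodes$left[i]] <- i
      parent[nodes$right[i]] <- i
    }
  }

  captured <- rep(FALSE, n_nodes)
  for (i in which(cot)) {
    l <- nodes$left[i]; r <- nodes$right[i]
    leaf_children <- c(l, r)[nodes$is_leaf[c(l, r)]]
    if (length(leaf_children) == 2L) leaf_children <- r
    captured[leaf_children] <- TRUE
  }

  part <- parent != 0L   # the root product never waits for a partner
  exposure <- ifelse(part, ready[pmax(parent, 1L)] - ready, 0)
  exposure[captured] <- 0

  tibble(
    node = seq_len(n_nodes),
    label = nodes$label,
    is_leaf = nodes$is_leaf,
    join_id = nodes$join_id,
    cotranslational = cot,
    captured = captured,
    parent = parent,
    wait = ifelse(nodes$is_leaf, NA_real_, wait),
    ready = ready,
    exposure = ifelse(part, exposure, NA_real_))
}

#' Closed-form expected yield of an assembly pathway
#'
#' Under deterministic level-synchronous waits, the expected fraction of
#' started assemblies that finish is
#' `Y = prod(s_eff over joins) * exp(-lambda * sum(a_u over parts))`:
#' every join must win the specificity competition, and every part must
#' survive the orphan hazard over its exposure time `a_u` (from its birth
#' to its joining; co-translationally captured leaves have `a_u = 0`).
#'
#' @param pathway An [assembly_pathway()].
#' @return A `yield_result` with elements `yield`, `specificity_component`,
#'   `hazard_component`, `total_exposure`, `exposures` (per-part tibble),
#'   `n_subunits`, `n_joins`; see also [tidy.yield_result()] and
#'   [glance.yield_result()].
#' @export
closed_form_yield <- function(pathway) {
  stopifnot(inherits(pathway, "assembly_pathway"))
  sched <- pathway_schedule(pathway)
  s_eff <- ifelse(sched$cotranslational[!sched$is_leaf],
                  effective_specificity(pathway$s, pathway$delta),
                  pathway$s)
  specificity <- prod(s_eff)
  total_exposure <- sum(sched$exposure, na.rm = TRUE)
  hazard <- exp(-pathway$lambda * total_exposure)
  structure(
    list(yield = specificity * hazard,
         specificity_component = specificity,
         hazard_component = hazard,
         total_exposure = total_exposure,
         exposures = sched,
         n_subunits = sum(sched$is_leaf),
         n_joins = sum(!sched$is_leaf),
         pathway = pathway,
         method = "closed_form"),
    class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf(
    "<yield_result/%s> yield %.4g (specificity %.4g x hazard %.4g); %d subunits, total exposure %g\n",
    x$method, x$yield, x$specificity_component, x$hazard_component,
    x$n_subunits, x$total_exposure))
  if (!is.null(x$n_trials)) {
    cat(sprintf("  Monte-Carlo: %d/%d successes, SE %.3g\n",
                x$successes, x$n_trials, x$se))
  }
  invisible(x)
}

#' Per-part exposure table of a yield result
#'
#' @param x A `yield_result`.
#' @param ... Unused.
#' @return Tibble of parts with birth (`ready` for intermediates, 0 for
#'   leaves), join schedule and orphan `exposure`.
#' @method tidy yield_result
#' @export
tidy.yield_result <- function(x, ...) x$exposures

#' One-row summary of a yield result
#'
#' @param x A `yield_result`.
#' @param ... Unused.
#' @return Tibble with `yield`, its components, `total_exposure`,
#'   `n_subunits`, `n_joins` and (for Monte-Carlo results) `n_trials`,
#'   `successes`, `se`.
#' @method glance yield_result
#' @export
glance.yield_result <- function(x, ...) {
  tibble(
    method = x$method,
    yield = x$yield,
    specificity_component = x$specificity_component,
    hazard_component = x$hazard_component,
    total_exposure = x$total_exposure,
    n_subunits = x$n_subunits,
    n_joins = x$n_joins,
    n_trials = x$n_trials %||% NA_integer_,
    successes = x$successes %||% NA_integer_,
    se = x$se %||% NA_real_)
}

#' Yield as a function of subunit number
#'
#' Evaluates the closed-form yield over a range of complex sizes for one or
#' both stereotyped topologies. For a sequential chain without hazard the
#' curve is exactly `Y = s^(n-1)`, i.e. log-linear with slope `log(s)`
#' (exponential decay of yield with subunit number); a positive hazard adds
#' a quadratic exposure term `-lambda * tau * n^2 / 2` that makes `log Y`
#' concave. The fitted log-linear slope of the sequential curve is attached
#' as attribute `log_slope`.
#'
#' @param n_range Integer vector of subunit counts (within `[1, 64]`).
#' @param s,lambda,tau,delta Model parameters, as in [assembly_pathway()].
#' @param topology `"sequential"` (default), `"balanced"`, or both.
#' @return A `yield_curve` tibble: `n`, `topology`, `yield`,
#'   `total_exposure`.
#' @export
yield_vs_n <- function(n_range, s = 0.9, lambda = 0.1, tau = 1,
                       delta = 1,
                       topology = "sequential") {
  topology <- match.arg(topology, c("sequential", "balanced"),
                        several.ok = TRUE)
  if (any(n_range < 1 | n_range > 64)) {
    abort("`n_range` must lie within [1, 64].")
  }
  grid <- tidyr::expand_grid(topology = topology, n = as.integer(n_range))
  curve <- purrr::pmap_dfr(grid, function(topology, n) {
    y <- closed_form_yield(assembly_pathway(
      n, s = s, lambda = lambda, tau = tau, delta = delta,
      topology = topology))
    tibble(n = n, topology = topology, yield = y$yield,
           total_exposure = y$total_exposure)
  })
  log_slope <- NA_real_
  seq_curve <- curve[curve$topology == "sequential", , drop = FALSE]
  if (nrow(seq_curve) >= 2 && all(seq_curve$yield > 0)) {
    log_slope <- unname(coef(lm(log(yield) ~ n, data = seq_curve))[2L])
  }
  structure(curve, class = c("yield_curve", class(curve)),
            log_slope = log_slope, s = s, lambda = lambda, tau = tau)
}

#' Monte-Carlo simulation of assembly success
#'
#' Simulates individual assembly attempts: each join wins its specificity
#' competition with probability `s_eff`, and each part survives the orphan
#' hazard over its exposure with probability `exp(-lambda * a_u)`. In
#' `waits = "deterministic"` mode exposures equal the closed-form schedule,
#' so the estimate is an unbiased oracle for [closed_form_yield()]; in
#' `waits = "exponential"` mode each diffusive join instead draws an
#' exponential waiting time with mean `tau` (co-translational joins keep
#' their fixed `tau_tr`), and exposures vary per trial.
#'
#' @param pathway An [assembly_pathway()].
#' @param n_trials Number of simulated assembly attempts (>= 1).
#' @param seed Integer seed.
#' @param waits `"deterministic"` or `"exponential"`.
#' @return A `yield_result` whose `yield` is the success fraction, with
#'   `n_trials`, `successes` and the binomial `se`.
#' @export
simulate_assembly <- function(pathway, n_trials = 20000L, seed = 1L,
                              waits = c("deterministic", "exponential")) {
  stopifnot(inherits(pathway, "assembly_pathway"))
  waits <- match.arg(waits)
  check_number(n_trials, "n_trials", lower = 1, integerish = TRUE)
  n_trials <- as.integer(n_trials)
  nodes <- pathway$nodes
  sched <- pathway_schedule(pathway)
  s_eff_join <- ifelse(sched$cotranslational[!sched$is_leaf],
                       effective_specificity(pathway$s, pathway$delta),
                       pathway$s)

  ok <- with_seed(seed, {
    ok <- rep(TRUE, n_trials)
    for (se in s_eff_join) ok <- ok & (runif(n_trials) < se)

    if (waits == "deterministic") {
      for (a in sched$exposure[!is.na(sched$exposure)]) {
        if (a > 0 && pathway$lambda > 0) {
          ok <- ok & (runif(n_trials) < exp(-pathway$lambda * a))
        }
      }
      ok
    } else {
      n_nodes <- nrow(nodes)
      ready <- matrix(0, nrow = n_trials, ncol = n_nodes)
      for (i in seq_len(n_nodes)) {
        if (!nodes$is_leaf[i]) {
          w <- if (sched$cotranslational[i]) {
            rep(pathway$tau_tr, n_trials)
          } else if (pathway$tau > 0) {
            rexp(n_trials, rate = 1 / pathway$tau)
          } else {
            rep(0, n_trials)
          }
          ready[, i] <- pmax(ready[, nodes$left[i]], ready[, nodes$right[i]]) + w
        }
      }
      if (pathway$lambda > 0) {
        for (u in which(sched$parent != 0L & !sched$captured)) {
          a <- ready[, sched$parent[u]] - ready[, u]
          ok <- ok & (runif(n_trials) < exp(-pathway$lambda * a))
        }
      }
      ok
    }
  })

  successes <- sum(ok)
  est <- successes / n_trials
  cf <- closed_form_yield(pathway)
  structure(
    list(yield = est,
         specificity_component = prod(s_eff_join),
         hazard_component = if (prod(s_eff_join) > 0) est / prod(s_eff_join) else NA_real_,
         total_exposure = cf$total_exposure,
         exposures = cf$exposures,
         n_subunits = cf$n_subunits,
         n_joins = cf$n_joins,
         pathway = pathway,
         method = paste0("monte_carlo_", waits),
         n_trials = n_trials,
         successes = successes,
         se = sqrt(est * (1 - est) / n_trials)),
    class = "yield_result")
}

#' Compare two assembly pathways
#'
#' Computes the closed-form yield of two pathways over the same number of
#' subunits and reports which failure component (specificity, hazard, or
#' both) drives the difference.
#'
#' @param pathway_a,pathway_b [assembly_pathway()] objects with equal
#'   subunit counts.
#' @return One-row tibble: `yield_a`, `yield_b`, `ratio` (a/b),
#'   `specificity_a/b`, `hazard_a/b`, `differs` (`"specificity"`,
#'   `"hazard"`, `"both"` or `"none"`).
#' @export
compare_pathways <- function(pathway_a, pathway_b) {
  ya <- closed_form_yield(pathway_a)
  yb <- closed_form_yield(pathway_b)
  if (ya$n_subunits != yb$n_subunits) {
    abort(sprintf("Pathways assemble different subunit counts (%d vs %d).",
                  ya$n_subunits, yb$n_subunits))
  }
  tol <- 1e-12
  spec_diff <- abs(ya$specificity_component - yb$specificity_component) > tol
  haz_diff <- abs(ya$hazard_component - yb$hazard_component) > tol
  differs <- if (spec_diff && haz_diff) "both"
  else if (spec_diff) "specificity"
  else if (haz_diff) "hazard"
  else "none"
  tibble(
    yield_a = ya$yield, yield_b = yb$yield,
    ratio = ya$yield / yb$yield,
    specificity_a = ya$specificity_component,
    specificity_b = yb$specificity_component,
    hazard_a = ya$hazard_component,
    hazard_b = yb$hazard_component,
    differs = differs)
}
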