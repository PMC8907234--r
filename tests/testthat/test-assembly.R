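test_that("pathway construction validates its inputs", {
  expect_error(assembly_pathway(4, s = 0), "`s`")
  expect_error(assembly_pathway(4, lambda = -1), "lambda")
  expect_error(assembly_pathway(4, tau = -0.1), "tau")
  expect_error(assembly_pathway(4, delta = 0.5), "delta")
  expect_error(assembly_pathway(list("A", list("B"))), "two children")
  expect_error(assembly_pathway(list("A", "A")), "unique")
  p <- sequential_pathway(4)
  expect_equal(sum(p$nodes$is_leaf), 4L)
  expect_equal(sum(!p$nodes$is_leaf), 3L)
})

test_that("yield is 1 when nothing can fail", {
  expect_equal(closed_form_yield(sequential_pathway(6, s = 1, lambda = 0))$yield, 1)
  expect_equal(closed_form_yield(balanced_pathway(8, s = 1, lambda = 0))$yield, 1)
  expect_equal(closed_form_yield(sequential_pathway(1, s = 0.5,
                                                    lambda = 2))$yield, 1)
})

test_that("the four-subunit chain and balanced tree match the hand-derived yields", {
  chain <- sequential_pathway(4, s = 0.9, lambda = 0.1, tau = 1)
  y_chain <- closed_form_yield(chain)
  # exposures: leaves 1, 1, 2, 3; intermediates 1, 1 -> total 9
  expect_equal(y_chain$total_exposure, 9)
  expect_equal(y_chain$yield, 0.9^3 * exp(-0.9))
  expect_equal(y_chain$yield, 0.2964, tolerance = 1e-3)

  tree <- balanced_pathway(4, s = 0.9, lambda = 0.1, tau = 1)
  y_tree <- closed_form_yield(tree)
  # exposures: four leaves at 1, two dimers at 1 -> total 6
  expect_equal(y_tree$total_exposure, 6)
  expect_equal(y_tree$yield, 0.9^3 * exp(-0.6))
  expect_equal(y_tree$yield, 0.4001, tolerance = 1e-3)
  expect_gt(y_tree$yield, y_chain$yield)
})

test_that("yield decays exponentially with subunit number", {
  curve0 <- yield_vs_n(1:12, s = 0.9, lambda = 0)
  expect_equal(curve0$yield[curve0$n == 1], 1)
  expect_equal(curve0$yield, 0.9^(curve0$n - 1))
  expect_equal(attr(curve0, "log_slope"), log(0.9), tolerance = 1e-10)

  # with hazard, log-yield gains a quadratic term with coefficient -lambda*tau/2
  curve1 <- yield_vs_n(2:30, s = 0.9, lambda = 0.05, tau = 2)
  fit <- lm(log(yield) ~ n + I(n^2), data = as.data.frame(curve1))
  expect_equal(unname(coef(fit)["I(n^2)"]), -0.05 * 2 / 2, tolerance = 0.01)
})

test_that("Monte-Carlo simulation agrees with the closed form", {
  p <- sequential_pathway(4, s = 0.9, lambda = 0.1, tau = 1)
  mc <- simulate_assembly(p, n_trials = 20000L, seed = 10L)
  cf <- closed_form_yield(p)
  expect_lt(abs(mc$yield - cf$yield), 3 * mc$se)

  sure <- simulate_assembly(sequential_pathway(5, s = 1, lambda = 0),
                            n_trials = 500L, seed = 1L)
  expect_equal(sure$yield, 1)
  expect_identical(simulate_assembly(p, n_trials = 1000L, seed = 3L)$yield,
                   simulate_assembly(p, n_trials = 1000L, seed = 3L)$yield)
})

test_that("exponential waits raise the survival odds over fixed waits", {
  # E[exp(-lambda A)] >= exp(-lambda E[A]) by Jensen: random waits help
  p <- sequential_pathway(6, s = 1, lambda = 0.2, tau = 1)
  det <- simulate_assembly(p, n_trials = 20000L, seed = 5L,
                           waits = "deterministic")
  exp_w <- simulate_assembly(p, n_trials = 20000L, seed = 5L,
                             waits = "exponential")
  expect_gt(exp_w$yield, det$yield - 3 * det$se)
  expect_gt(exp_w$yield, det$yield)
})

test_that("pathway comparison finds hierarchy and capture advantages", {
  chain <- sequential_pathway(8, s = 0.95, lambda = 0.05)
  tree <- balanced_pathway(8, s = 0.95, lambda = 0.05)
  cmp <- compare_pathways(tree, chain)
  expect_gte(cmp$yield_a, cmp$yield_b)
  expect_equal(cmp$differs, "hazard")

  # flagging any join co-translational never lowers the yield
  for (j in 1:7) {
    flagged <- sequential_pathway(8, s = 0.95, lambda = 0.05,
                                  cotranslational = j, delta = 3)
    expect_gte(closed_form_yield(flagged)$yield,
               closed_form_yield(chain)$yield)
  }

  # delta = 1 and tau_tr = tau: the flag only zeroes the captured leaf
  neutral <- sequential_pathway(4, s = 0.9, lambda = 0.1,
                                cotranslational = 2L, delta = 1)
  plain <- sequential_pathway(4, s = 0.9, lambda = 0.1)
  y_n <- closed_form_yield(neutral)
  y_p <- closed_form_yield(plain)
  expect_equal(y_n$specificity_component, y_p$specificity_component)
  sched_n <- tidy(y_n); sched_p <- tidy(y_p)
  diff_parts <- which(sched_n$exposure != sched_p$exposure)
  expect_equal(sched_n$captured[diff_parts], TRUE)
  expect_equal(y_p$total_exposure - y_n$total_exposure,
               sched_p$exposure[diff_parts])

  expect_error(compare_pathways(chain, sequential_pathway(5)), "different")
})

test_that("yield respects its monotonicities and stays within [0, 1]", {
  withr::with_seed(20L, {
    for (i in 1:20) {
      n <- sample(2:16, 1)
      s <- runif(1, 0.5, 1)
      lambda <- runif(1, 0, 0.3)
      tau <- runif(1, 0.1, 2)
      topo <- sample(c("sequential", "balanced"), 1)
      y <- closed_form_yield(assembly_pathway(n, s = s, lambda = lambda,
                                              tau = tau, topology = topo))$yield
      expect_gte(y, 0); expect_lte(y, 1)
      y_s <- closed_form_yield(assembly_pathway(n, s = min(1, s + 0.05),
                                                lambda = lambda, tau = tau,
                                                topology = topo))$yield
      y_l <- closed_form_yield(assembly_pathway(n, s = s,
                                                lambda = lambda + 0.1,
                                                tau = tau, topology = topo))$yield
      y_n <- closed_form_yield(assembly_pathway(n + 1, s = s, lambda = lambda,
                                                tau = tau, topology = topo))$yield
      expect_gte(y_s, y)
      expect_lte(y_l, y)
      expect_lte(y_n, y)
    }
  })
})

test_that("balanced trees beat chains exactly when there is hazard", {
  for (n in c(2, 3, 8, 16, 33, 64)) {
    y_b <- closed_form_yield(balanced_pathway(n, s = 0.9, lambda = 0.05))
    y_s <- closed_form_yield(sequential_pathway(n, s = 0.9, lambda = 0.05))
    expect_gte(y_b$yield, y_s$yield)
    y_b0 <- closed_form_yield(balanced_pathway(n, s = 0.9, lambda = 0))
    y_s0 <- closed_form_yield(sequential_pathway(n, s = 0.9, lambda = 0))
    expect_equal(y_b0$yield, y_s0$yield)
  }
})

test_that("tidy and glance expose the schedule and summary", {
  y <- closed_form_yield(sequential_pathway(4, s = 0.9, lambda = 0.1))
  sched <- tidy(y)
  expect_equal(sum(sched$is_leaf), 4L)
  expect_equal(sum(sched$exposure, na.rm = TRUE), y$total_exposure)
  g <- glance(y)
  expect_equal(g$yield, y$yield)
  expect_equal(g$n_joins, 3L)
})
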