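# Decomposable BIC family scores: closed-form checks against independent
# fits, penalty behaviour, and decomposability.

test_that("Gaussian family score matches an independently fitted OLS + BIC", {
  d <- data.frame(x = c(0, 1, 2, 3, 4), y = c(0.1, 2.1, 3.9, 6.2, 7.9))
  fs <- score_gaussian_family(d, "y", "x")
  # oracle: lm() fit, MLE variance, explicit penalty bookkeeping
  fit <- lm(y ~ x, d)
  n <- 5
  s2 <- sum(residuals(fit)^2) / n
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  expect_equal(fs$loglik, ll, tolerance = 1e-9)
  expect_equal(fs$k, 3L)
  expect_equal(fs$bic, ll - 1.5 * log(n), tolerance = 1e-9)
  expect_equal(fs$bic, fs$loglik - fs$k / 2 * log(fs$n), tolerance = 1e-12)
  expect_equal(unname(fs$coefs), unname(coef(fit)), tolerance = 1e-8)
})

test_that("the BIC penalty rejects an independent candidate parent", {
  wins <- 0L
  for (s in 1:200) {
    set.seed(s)
    d <- data.frame(a = rnorm(1000), b = rnorm(1000))
    wins <- wins + (score_gaussian_family(d, "b")$bic >
                      score_gaussian_family(d, "b", "a")$bic)
  }
  expect_gte(wins / 200, 0.95)
})

test_that("zero residual variance is flagged degenerate and excluded from search", {
  set.seed(1)
  d <- data.frame(a = rnorm(50))
  d$b <- 2 * d$a
  fs <- score_gaussian_family(d, "b", "a")
  expect_true(fs$degenerate)
  expect_identical(fs$bic, Inf)
  cand <- enumerate_families(d, "b", search_config(max_parents = 1))
  expect_false(any(vapply(cand$ranked, `[[`, TRUE, "degenerate")))
  expect_error(score_gaussian_family(d[1:3, ], "b", "a"),
               class = "insufficient_data")
})

test_that("multinomial score has the documented closed forms", {
  d <- data.frame(y = factor(rep(1:2, each = 5)))
  fs <- score_multinomial_family(d, "y", alpha = 0)
  expect_equal(fs$loglik, 10 * log(0.5), tolerance = 1e-12)
  expect_equal(fs$k, 1L)

  # alpha = 0 equals plain MLE log-likelihood minus the penalty
  set.seed(7)
  d2 <- data.frame(a = factor(sample(1:2, 400, TRUE)),
                   b = factor(sample(1:3, 400, TRUE)))
  fs2 <- score_multinomial_family(d2, "b", "a", alpha = 0)
  tab <- table(d2$a, d2$b)
  mle <- sum(tab * log(tab / rowSums(tab)))
  expect_equal(fs2$loglik, mle, tolerance = 1e-9)
  expect_equal(fs2$bic, mle - (3 - 1) * 2 / 2 * log(400), tolerance = 1e-9)

  # deterministic dependence: the parent family wins
  set.seed(8)
  a <- factor(sample(1:2, 1000, TRUE))
  d3 <- data.frame(a = a, b = a)
  expect_gt(score_multinomial_family(d3, "b", "a")$bic,
            score_multinomial_family(d3, "b")$bic)

  expect_error(score_multinomial_family(
    data.frame(a = rnorm(10), b = factor(rep(1:2, 5))), "b", "a"),
    class = "mixed_constraint")
})

test_that("unobserved parent configurations contribute nothing", {
  # parent level 3 never observed: its posterior row is uniform, loglik
  # comes only from observed rows
  d <- data.frame(a = factor(c(1, 1, 2, 2), levels = 1:3),
                  b = factor(c(1, 2, 1, 2)))
  fs0 <- score_multinomial_family(d, "b", "a", alpha = 0)
  expect_equal(fs0$loglik, 4 * log(0.5), tolerance = 1e-12)
  expect_equal(fs0$k, (2 - 1) * 3)
})

test_that("conditional-Gaussian scoring reduces, separates and pools correctly", {
  set.seed(11)
  n <- 1000
  d <- data.frame(x = rnorm(n), g = factor(sample(1:2, n, TRUE)))
  d$y <- 1.5 * d$x + 4 * (as.integer(d$g) - 1) + rnorm(n)

  # no discrete parents: identical to the Gaussian score
  expect_equal(score_cgaussian_family(d, "y", "x")$bic,
               score_gaussian_family(d, "y", "x")$bic, tolerance = 1e-9)

  # a 4-sigma mean shift is worth its parameter
  expect_gt(score_cgaussian_family(d, "y", c("x", "g"))$bic,
            score_gaussian_family(d, "y", "x")$bic)

  # all rows in one configuration: one intercept, same k as the plain fit
  d1 <- d
  d1$g <- factor(rep(1, n))
  fs <- score_cgaussian_family(d1, "y", c("x", "g"))
  expect_equal(fs$k, score_gaussian_family(d, "y", "x")$k)
  expect_equal(fs$loglik, score_gaussian_family(d1, "y", "x")$loglik,
               tolerance = 1e-9)
})

test_that("global BIC decomposes into family scores on random DAG/data pairs", {
  for (s in 1:25) {
    kind <- if (s %% 2) "continuous" else "mixed"
    inst <- simulate_instance(sim_config(network_kind = kind, p = 8, n = 60,
                                         seed = 400 + s))
    ctx <- score_context(inst$data)
    dag <- inst$truth$dag
    total <- sum(vapply(dag$nodes, function(v)
      score_family(ctx, v, parents_of(dag, v))$bic, 0))
    expect_equal(global_bic(dag, ctx), total, tolerance = 1e-9)
  }
})

test_that("family scores ignore unrelated columns and column order", {
  set.seed(21)
  d <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  d$b <- d$b + d$a
  f1 <- score_gaussian_family(d, "b", "a")
  f2 <- score_gaussian_family(d[, c("c", "b", "a")], "b", "a")
  d$c <- rnorm(200) # permuting/replacing other columns must not matter
  f3 <- score_gaussian_family(d, "b", "a")
  expect_identical(f1$bic, f2$bic)
  expect_identical(f1$bic, f3$bic)
})

test_that("true families beat single-edge perturbations at large n", {
  inst <- simulate_instance(sim_config(p = 8, n = 10000, seed = 77))
  ctx <- score_context(inst$data)
  dag <- inst$truth$dag
  nodes <- dag$nodes
  ok <- 0L
  tot <- 0L
  for (v in nodes) {
    pa <- parents_of(dag, v)
    true_bic <- score_family(ctx, v, pa)$bic
    # deletions of a true parent, and additions of a non-descendant
    # non-parent (descendants carry information about v by construction,
    # so only acyclicity-respecting additions are fair perturbations)
    addable <- setdiff(nodes, c(v, pa, descendants_in(dag, v)))
    alt <- c(lapply(pa, function(u) setdiff(pa, u)),
             lapply(addable, function(u) sort(c(pa, u))))
    for (s in alt) {
      tot <- tot + 1L
      ok <- ok + (true_bic > score_family(ctx, v, s)$bic)
    }
  }
  expect_gte(ok / tot, 0.95)
})

test_that("adding a true edge back improves the global BIC", {
  wins <- 0L
  runs <- 40L
  for (s in 1:runs) {
    inst <- simulate_instance(sim_config(p = 6, n = 1000, seed = 500 + s,
                                         shuffle_columns = FALSE))
    dag <- inst$truth$dag
    if (!nrow(dag$edges)) { runs <- runs - 1L; next }
    drop <- dag$edges[1, ]
    reduced <- typed_dag(
      data.frame(name = dag$nodes, kind = dag$kind, levels = dag$levels),
      dag$edges[-1, ])
    ctx <- score_context(inst$data)
    wins <- wins + (global_bic(dag, ctx) > global_bic(reduced, ctx))
  }
  expect_gte(wins / runs, 0.95)
})
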