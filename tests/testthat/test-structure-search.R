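# Two-phase learner: family enumeration, acyclic assembly (greedy and
# exact), the full learn() surface and the hill-climbing baseline.

test_that("enumerate_families is exhaustive on tiny cases and respects types", {
  set.seed(1)
  d <- data.frame(a = rnorm(100), b = rnorm(100))
  cand <- enumerate_families(d, "b", search_config(max_parents = 1))
  sets <- lapply(cand$ranked, `[[`, "parents")
  expect_setequal(vapply(sets, paste, "", collapse = ","), c("", "a"))

  # ranking is strictly sorted: bic desc, then fewer parents, then names
  set.seed(2)
  d3 <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  d3$y <- d3$a + rnorm(200)
  cand3 <- enumerate_families(d3, "y", search_config(max_parents = 2))
  bics <- vapply(cand3$ranked, `[[`, 0, "bic")
  expect_true(all(diff(bics) <= 1e-12))

  # discrete child: continuous columns never enter a candidate family
  set.seed(3)
  dm <- data.frame(x = rnorm(150), g = factor(sample(1:2, 150, TRUE)),
                   h = factor(sample(1:2, 150, TRUE)))
  cm <- enumerate_families(dm, "g", search_config(max_parents = 2))
  pa <- unlist(lapply(cm$ranked, `[[`, "parents"))
  expect_false("x" %in% pa)
})

test_that("the middle node of a chain screens off its grandparent", {
  wins <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 1000
    d <- data.frame(A = rnorm(n))
    d$B <- 2 * d$A + rnorm(n)
    d$C <- 2 * d$B + rnorm(n)
    cand <- enumerate_families(d, "C", search_config(max_parents = 1))
    top <- cand$ranked[[1]]$parents
    wins <- wins + identical(top, "B")
  }
  expect_gte(wins / 100, 0.90)
})

test_that("staged enumeration stays within budget and still finds strong families", {
  set.seed(4)
  n <- 300
  d <- as.data.frame(matrix(rnorm(n * 12), n))
  names(d) <- sprintf("V%02d", 1:12)
  d$V12 <- d$V01 + d$V02 + rnorm(n)
  cand <- enumerate_families(d, "V12",
                             search_config(max_parents = 4, subset_budget = 100))
  expect_true(cand$staged)
  expect_lte(cand$n_scored, 400)
  top <- cand$ranked[[1]]$parents
  expect_true(all(c("V01", "V02") %in% top))
})

test_that("acyclic top families are returned untouched by the assembler", {
  set.seed(5)
  n <- 500
  d <- data.frame(A = rnorm(n), B = rnorm(n)) # independent: tops are empty
  cfg <- search_config(max_parents = 1, restarts = 0)
  cands <- lapply(c("A", "B"), function(v) enumerate_families(d, v, cfg))
  res <- assemble_greedy(cands, cfg)
  expect_equal(res$repairs, 0L)
  expect_equal(nrow(res$dag$edges), 0L)
  tops <- lapply(cands, function(cn) cn$ranked[[1]])
  expect_equal(res$global_bic,
               sum(vapply(tops, `[[`, 0, "bic")), tolerance = 1e-9)
})

test_that("a two-node tie-cycle keeps the direction whose demotion costs more", {
  # hand-built candidate lists: A's top family {B}, B's top family {A};
  # B loses more by demotion, so A is demoted and B -> A ... i.e. the edge
  # A <- B survives? No: demoting A removes A's parent B, keeping A -> B?
  # A's family is (A | B), i.e. edge B -> A.  Demoting A (cost 1) keeps
  # B's family (B | A): the surviving edge is A -> B.
  mk <- function(child, other, bic_top, bic_empty) {
    structure(list(
      child = child,
      ranked = list(
        structure(list(child = child, parents = other, bic = bic_top,
                       loglik = bic_top, k = 3L, n = 10L, degenerate = FALSE),
                  class = "family_score"),
        structure(list(child = child, parents = character(0), bic = bic_empty,
                       loglik = bic_empty, k = 2L, n = 10L, degenerate = FALSE),
                  class = "family_score")),
      staged = FALSE, n_scored = 2L, child_kind = "continuous",
      child_levels = NA_integer_), class = "family_candidates")
  }
  cands <- list(mk("A", "B", -10, -11), # demoting A costs 1
                mk("B", "A", -10, -13)) # demoting B costs 3
  res <- assemble_greedy(cands, search_config(restarts = 0))
  expect_equal(res$dag$edges$parent, "A")
  expect_equal(res$dag$edges$child, "B")
  expect_equal(res$repairs, 1L)
})

test_that("exact DP equals brute force over all labeled 4-node DAGs", {
  for (s in 1:6) {
    inst <- simulate_instance(sim_config(p = 4, n = 80, seed = 600 + s,
                                         mean_parents = 1.2))
    d <- inst$data
    cfg <- search_config(max_parents = 3, candidates_per_node = 50)
    cands <- lapply(sort(names(d)), function(v) enumerate_families(d, v, cfg))
    res <- assemble_exact_dp(cands, cfg)
    expect_equal(res$global_bic, brute_force_best_bic(d, 3), tolerance = 1e-9)
    expect_silent(topological_order(res$dag))
  }
})

test_that("exact DP dominates the greedy assembler and agrees on most instances", {
  agree <- 0L
  runs <- 30L
  for (s in 1:runs) {
    inst <- simulate_instance(sim_config(p = 6, n = 300, seed = 700 + s))
    d <- inst$data
    cfg <- search_config(max_parents = 3)
    cands <- lapply(sort(names(d)), function(v) enumerate_families(d, v, cfg))
    gr <- assemble_greedy(cands, cfg)
    dp <- assemble_exact_dp(cands, cfg)
    expect_lte(gr$global_bic, dp$global_bic + 1e-9)
    agree <- agree + (abs(gr$global_bic - dp$global_bic) < 1e-6)
  }
  expect_gte(agree / runs, 0.8)
})

test_that("exact DP refuses oversized problems and handles a single node", {
  set.seed(6)
  d1 <- data.frame(a = rnorm(30))
  cfg <- search_config()
  c1 <- list(enumerate_families(d1, "a", cfg))
  res <- assemble_exact_dp(c1, cfg)
  expect_equal(nrow(res$dag$edges), 0L)
  expect_equal(res$global_bic, score_gaussian_family(d1, "a")$bic,
               tolerance = 1e-9)

  fake <- lapply(1:21, function(i) {
    structure(list(child = sprintf("N%02d", i),
                   ranked = list(), staged = FALSE, n_scored = 0L,
                   child_kind = "continuous", child_levels = NA_integer_),
              class = "family_candidates")
  })
  expect_error(assemble_exact_dp(fake, cfg), class = "size_limit")
})

test_that("learn recovers a strong two-node signal and rejects pure noise", {
  hits <- 0L
  empties <- 0L
  for (s in 1:60) {
    set.seed(s)
    n <- 1000
    d <- data.frame(A = rnorm(n))
    d$B <- 2 * d$A + rnorm(n)
    fit <- learn(d, search_config(max_parents = 1))
    adj <- nrow(fit$dag$edges) == 1L &&
      setequal(c(fit$dag$edges$parent, fit$dag$edges$child), c("A", "B"))
    hits <- hits + adj

    set.seed(1000 + s)
    dn <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    fitn <- learn(dn, search_config(max_parents = 2))
    empties <- empties + (nrow(fitn$dag$edges) == 0L)
  }
  expect_gte(hits / 60, 0.95)
  expect_gte(empties / 60, 0.90)
})

test_that("learning is invariant to the dataset's column order", {
  inst <- simulate_instance(sim_config(p = 8, n = 300, seed = 42))
  d <- inst$data
  f1 <- learn(d)
  f2 <- learn(d[, rev(names(d))])
  expect_identical(f1$dag$edges, f2$dag$edges)
  expect_identical(f1$global_bic, f2$global_bic)
})

test_that("learner output is deterministic and always a valid typed DAG", {
  for (s in 1:5) {
    inst <- simulate_instance(sim_config(network_kind = "mixed", p = 8,
                                         n = 150, seed = 800 + s))
    f1 <- learn(inst$data, search_config(max_parents = 2))
    f2 <- learn(inst$data, search_config(max_parents = 2))
    expect_identical(f1$dag, f2$dag)
    expect_silent(topological_order(f1$dag))
    ed <- f1$dag$edges
    if (nrow(ed)) {
      bad <- f1$dag$kind[ed$child] == "discrete" &
        f1$dag$kind[ed$parent] == "continuous"
      expect_false(any(bad))
    }
  }
})

test_that("learned edge weights carry the fitted coefficients", {
  # collider A -> C <- B: the v-structure makes the directions identifiable
  set.seed(9)
  n <- 2000
  d <- data.frame(A = rnorm(n), B = rnorm(n))
  d$C <- 2 * d$A - 1.5 * d$B + rnorm(n)
  fit <- learn(d, search_config(max_parents = 2))
  ed <- fit$edges
  expect_equal(sort(ed$parent), c("A", "B"))
  expect_equal(ed$child, c("C", "C"))
  expect_equal(ed$weight[ed$parent == "A"], 2, tolerance = 0.1)
  expect_equal(ed$weight[ed$parent == "B"], -1.5, tolerance = 0.1)
})

test_that("hill climbing ascends monotonically and stops on independent data", {
  set.seed(10)
  d <- data.frame(a = rnorm(800), b = rnorm(800), c = rnorm(800))
  fit <- hill_climb_baseline(d)
  expect_equal(nrow(fit$dag$edges), 0L)

  inst <- simulate_instance(sim_config(p = 6, n = 400, seed = 55))
  hc <- hill_climb_baseline(inst$data)
  empty_bic <- sum(vapply(names(inst$data), function(v)
    score_gaussian_family(inst$data, v)$bic, 0))
  expect_gte(hc$global_bic, empty_bic)
  expect_silent(topological_order(hc$dag))
})

test_that("the two-phase learner matches or beats hill climbing on global BIC", {
  wins <- 0L
  runs <- 25L
  for (s in 1:runs) {
    inst <- simulate_instance(sim_config(p = 6, n = 300, seed = 900 + s))
    tp <- learn(inst$data, search_config(max_parents = 3))
    hc <- hill_climb_baseline(inst$data, search_config(max_parents = 3))
    wins <- wins + (tp$global_bic >= hc$global_bic - 1e-9)
  }
  expect_gte(wins / runs, 0.8)
})
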