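# Typed-DAG container, topology generators and joint-density factorization.

test_that("typed_dag validates names, endpoints, self-edges and the mixed constraint", {
  v <- cont_vars(c("A", "B"))
  expect_s3_class(typed_dag(v, edge_df(c("A", "B"))), "typed_dag")
  expect_error(typed_dag(cont_vars(c("A", "A"))), class = "invalid_argument")
  expect_error(typed_dag(v, edge_df(c("A", "Z"))), class = "invalid_structure")
  expect_error(typed_dag(v, edge_df(c("A", "A"))), class = "invalid_structure")
  expect_error(typed_dag(disc_vars("D", 1L)), class = "invalid_argument")
  mixed <- rbind(cont_vars("A"), disc_vars("D"))
  expect_error(typed_dag(mixed, edge_df(c("A", "D"))), class = "invalid_structure")
  expect_s3_class(typed_dag(mixed, edge_df(c("D", "A"))), "typed_dag")
})

test_that("topological_order sorts edges forward, breaks ties by name, rejects cycles", {
  expect_equal(topological_order(chain_dag()), c("A", "B", "C"))
  expect_equal(topological_order(typed_dag(cont_vars(c("C", "A", "B")))),
               c("A", "B", "C"))
  cyc <- list(nodes = c("A", "B"),
              edges = edge_df(c("A", "B"), c("B", "A")))
  expect_error(topological_order(cyc), class = "invalid_structure")
})

test_that("random DAG generator hits the density knob and its edge cases", {
  g0 <- generate_random_dag(10, mean_parents = 0, seed = 1)
  expect_equal(nrow(g0$edges), 0L)
  expect_length(g0$nodes, 10L)

  # maximal density for p = 3: inclusion probability 2*m/(p-1) = 1
  g3 <- generate_random_dag(3, mean_parents = 1, seed = 7)
  expect_equal(nrow(g3$edges), 3L)
  expect_silent(topological_order(g3))

  expect_error(generate_random_dag(0), class = "invalid_argument")
  expect_error(generate_random_dag(5, mean_parents = 5), class = "invalid_argument")
})

test_that("random DAG empirical mean in-degree matches mean_parents", {
  p <- 50
  target <- 1.5
  # Monte-Carlo estimate of the generator's expected in-degree
  mean_indeg <- mean(vapply(1:400, function(s)
    nrow(generate_random_dag(p, target, seed = s)$edges) / p, 0))
  expect_lt(abs(mean_indeg - target), 0.1)
})

test_that("generated DAGs are acyclic and mixed graphs never point continuous at discrete", {
  for (s in 1:350) {
    kind <- c("continuous", "discrete", "mixed")[1L + s %% 3L]
    g <- generate_random_dag(12, 1.5, kind = kind, seed = s)
    expect_silent(topological_order(g))
    if (nrow(g$edges)) {
      bad <- g$kind[g$edges$child] == "discrete" &
        g$kind[g$edges$parent] == "continuous"
      expect_false(any(bad))
      indeg <- table(g$edges$child)
      disc <- names(indeg)[g$kind[names(indeg)] == "discrete"]
      if (length(disc)) expect_true(all(indeg[disc] <= 3L))
    }
  }
})

test_that("same seed regenerates the identical graph", {
  a <- generate_random_dag(15, 1.5, kind = "mixed", seed = 42)
  b <- generate_random_dag(15, 1.5, kind = "mixed", seed = 42)
  expect_identical(a, b)
  a <- generate_scale_free_dag(30, 2, seed = 9)
  b <- generate_scale_free_dag(30, 2, seed = 9)
  expect_identical(a, b)
})

test_that("scale-free generator grows trees and rejects non-continuous kinds", {
  g2 <- generate_scale_free_dag(2, 1, seed = 0)
  expect_equal(nrow(g2$edges), 1L)

  g <- generate_scale_free_dag(500, 1, seed = 3)
  expect_equal(nrow(g$edges), 499L) # tree growth invariant
  expect_silent(topological_order(g))

  expect_error(generate_scale_free_dag(10, 1, kind = "discrete"),
               class = "unsupported_combination")
})

test_that("scale-free out-degree tails are heavier than random DAGs at equal edge count", {
  max_out <- function(edges) if (nrow(edges)) max(table(edges$parent)) else 0L
  sf <- vapply(1:40, function(s)
    max_out(generate_scale_free_dag(200, 1, seed = s)$edges), 0L)
  # random DAG at the same expected edge count (199 edges over 200 nodes)
  rnd <- vapply(1:40, function(s)
    max_out(generate_random_dag(200, 199 / 200, seed = s)$edges), 0L)
  expect_gt(mean(sf), 2 * mean(rnd))
})

test_that("log_joint factorizes and normalizes", {
  # two independent uniform binary nodes
  v <- disc_vars(c("A", "B"))
  dag <- typed_dag(v)
  net <- parameterized_network(dag, list(
    A = multinomial_cpd(matrix(0.5, 1, 2)),
    B = multinomial_cpd(matrix(0.5, 1, 2))))
  expect_equal(log_joint(net, list(A = 1, B = 2)), log(0.25))

  # standard normal root at its mode
  nc <- parameterized_network(typed_dag(cont_vars("X")),
                              list(X = lingauss_cpd(sigma2 = 1)))
  expect_equal(log_joint(nc, list(X = 0)), -0.5 * log(2 * pi))

  # hand-evaluated chain factorization
  dag2 <- typed_dag(disc_vars(c("A", "B")), edge_df(c("A", "B")))
  net2 <- parameterized_network(dag2, list(
    A = multinomial_cpd(matrix(c(0.3, 0.7), 1, 2)),
    B = multinomial_cpd(rbind(c(0.9, 0.1), c(0.2, 0.8)),
                        parent_levels = c(A = 2L))))
  expect_equal(log_joint(net2, list(A = 1, B = 2)), log(0.3) + log(0.1))
  expect_error(log_joint(net2, list(A = 3, B = 1)), class = "invalid_value")
})

test_that("exp(log_joint) sums to one over all configurations of small discrete networks", {
  for (s in 1:3) {
    cfg <- sim_config(network_kind = "discrete", p = 4, n = 5, seed = s,
                      levels_set = 2L)
    dag <- generate_random_dag(4, 1.2, kind = "discrete", levels_set = 2L,
                               seed = s)
    net <- draw_parameters(dag, cfg)
    grid <- expand.grid(rep(list(1:2), 4))
    names(grid) <- dag$nodes
    total <- sum(vapply(seq_len(nrow(grid)), function(i)
      exp(log_joint(net, as.list(grid[i, ]))), 0))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})
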