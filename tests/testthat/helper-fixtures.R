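# Shared fixture builders: tiny graphs, hand-parameterized networks and
# brute-force oracles used across the test files.

cont_vars <- function(names) {
  data.frame(name = names, kind = "continuous", levels = NA_integer_,
             stringsAsFactors = FALSE)
}

disc_vars <- function(names, levels = 2L) {
  data.frame(name = names, kind = "discrete",
             levels = rep_len(levels, length(names)), stringsAsFactors = FALSE)
}

edge_df <- function(...) {
  pairs <- list(...)
  data.frame(parent = vapply(pairs, `[`, "", 1L),
             child = vapply(pairs, `[`, "", 2L), stringsAsFactors = FALSE)
}

chain_dag <- function(names = c("A", "B", "C")) {
  typed_dag(cont_vars(names),
            edge_df(c(names[1], names[2]), c(names[2], names[3])))
}

# all labeled DAGs on the given nodes, as a list of edge data frames
# (brute-force enumeration: filter every directed graph for acyclicity)
all_dags <- function(nodes) {
  pairs <- expand.grid(parent = nodes, child = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$parent != pairs$child, ]
  np <- nrow(pairs)
  vars <- cont_vars(nodes)
  out <- list()
  for (code in 0:(2^np - 1)) {
    sel <- bitwAnd(code, 2^(seq_len(np) - 1)) > 0
    ed <- pairs[sel, , drop = FALSE]
    dag <- tryCatch(typed_dag(vars, ed), error = function(e) NULL)
    if (!is.null(dag)) out[[length(out) + 1L]] <- dag
  }
  out
}

# memoized family bic (shares the context's cache)
cached_score_for_test <- function(ctx, v, pa) {
  twophasebn:::cached_score(ctx, v, pa)$bic
}

# independent maximum over all labeled DAGs of the summed family BIC,
# with per-node in-degree capped; the pre-build oracle for exact assembly
brute_force_best_bic <- function(data, max_parents = 3L) {
  ctx <- score_context(data)
  nodes <- sort(names(data))
  best <- -Inf
  for (dag in all_dags(nodes)) {
    indeg <- table(factor(dag$edges$child, levels = nodes))
    if (any(indeg > max_parents)) next
    s <- sum(vapply(nodes, function(v)
      cached_score_for_test(ctx, v, parents_of(dag, v)), 0))
    if (s > best) best <- s
  }
  best
}

# all descendants of v in a typed_dag (child-edge BFS)
descendants_in <- function(dag, v) {
  out <- character(0)
  queue <- dag$edges$child[dag$edges$parent == v]
  while (length(queue)) {
    w <- queue[1L]
    queue <- queue[-1L]
    if (w %in% out) next
    out <- c(out, w)
    queue <- c(queue, dag$edges$child[dag$edges$parent == w])
  }
  out
}

# strict-direction classifier over ordered node pairs, written
# independently of compare_structures
brute_force_metrics <- function(truth, learned) {
  nodes <- sort(truth$nodes)
  tp <- fp <- fn <- 0L
  in_edges <- function(dag, u, v) any(dag$edges$parent == u & dag$edges$child == v)
  for (u in nodes) for (v in nodes) {
    if (u == v) next
    t <- in_edges(truth, u, v)
    l <- in_edges(learned, u, v)
    if (t && l) tp <- tp + 1L
    if (!t && l) fp <- fp + 1L
    if (t && !l) fn <- fn + 1L
  }
  p <- length(nodes)
  list(tp = tp, fp = fp, fn = fn,
       tpr = if (tp + fn > 0) tp / (tp + fn) else 1,
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       fpr = fp / (p * (p - 1) - nrow(truth$edges)))
}
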