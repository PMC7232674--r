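# Typed directed acyclic graphs: the container for both ground-truth and
# learned structures.  Variables carry a kind (continuous or discrete); a
# discrete child may only have discrete parents, which is the standard
# restriction for conditional-Gaussian Bayesian networks.

#' Construct a typed DAG
#'
#' A `typed_dag` couples a variable table (name, kind, number of levels for
#' discrete variables) with a set of directed edges, and validates the whole
#' object: unique names, existing endpoints, no self-edges, acyclicity, and
#' the mixed-network constraint that discrete children have only discrete
#' parents.
#'
#' @param variables Data frame with columns `name` (character, unique),
#'   `kind` (`"continuous"` or `"discrete"`) and, for discrete variables,
#'   `levels` (integer >= 2; `NA` for continuous variables).
#' @param edges Data frame with character columns `parent` and `child`, or
#'   `NULL` for an edgeless graph.
#' @return An object of class `typed_dag` with elements `nodes`, `kind`,
#'   `levels` (named vectors) and `edges` (data frame).
#' @export
#' @examples
#' v <- data.frame(name = c("A", "B"), kind = "continuous", levels = NA_integer_)
#' typed_dag(v, data.frame(parent = "A", child = "B"))
typed_dag <- function(variables, edges = NULL) {
  tpb_assert(is.data.frame(variables) && all(c("name", "kind") %in% names(variables)),
             "invalid_argument", "variables must be a data frame with name and kind columns")
  nm <- as.character(variables$name)
  kind <- as.character(variables$kind)
  tpb_assert(!anyDuplicated(nm), "invalid_argument", "variable names must be unique")
  tpb_assert(all(kind %in% c("continuous", "discrete")),
             "invalid_argument", "kind must be continuous or discrete")
  lev <- if ("levels" %in% names(variables)) as.integer(variables$levels) else rep(NA_integer_, length(nm))
  lev[kind == "continuous"] <- NA_integer_
  tpb_assert(all(!is.na(lev[kind == "discrete"]) & lev[kind == "discrete"] >= 2L),
             "invalid_argument", "discrete variables need levels >= 2")
  names(kind) <- nm
  names(lev) <- nm

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(parent = character(0), child = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(parent = as.character(edges$parent),
                        child = as.character(edges$child),
                        stringsAsFactors = FALSE)
    tpb_assert(all(edges$parent %in% nm) && all(edges$child %in% nm),
               "invalid_structure", "edge endpoints must be declared variables")
    tpb_assert(!any(edges$parent == edges$child), "invalid_structure", "self-edges are not allowed")
    edges <- unique(edges)
    bad <- kind[edges$child] == "discrete" & kind[edges$parent] == "continuous"
    tpb_assert(!any(bad), "invalid_structure",
               "a discrete child may only have discrete parents")
  }
  # canonical edge order: by child then parent, so serialization is stable
  edges <- edges[order(edges$child, edges$parent), , drop = FALSE]
  rownames(edges) <- NULL

  dag <- structure(list(nodes = nm, kind = kind, levels = lev, edges = edges),
                   class = "typed_dag")
  topological_order(dag) # acyclicity check; errors on a cycle
  dag
}

#' @export
print.typed_dag <- function(x, ...) {
  nd <- sum(x$kind == "discrete")
  cat(sprintf("typed_dag: %d nodes (%d discrete), %d edges\n",
              length(x$nodes), nd, nrow(x$edges)))
  invisible(x)
}

#' Parents of a node
#' @param dag A [typed_dag()].
#' @param node Node name.
#' @return Character vector of parent names, sorted.
#' @export
parents_of <- function(dag, node) {
  sort(dag$edges$parent[dag$edges$child == node])
}

#' Topological order of a typed DAG
#'
#' Kahn's algorithm with lexicographic tie-breaking among the currently
#' source nodes, so the order is a deterministic function of the graph.
#' Doubles as the acyclicity check used throughout the package.
#'
#' @param dag A [typed_dag()] (or a bare list with `nodes` and `edges`).
#' @return Character vector of node names; every edge goes from an earlier
#'   to a later position.
#' @export
#' @examples
#' v <- data.frame(name = c("C", "A", "B"), kind = "continuous", levels = NA)
#' topological_order(typed_dag(v, data.frame(parent = "A", child = "B")))
topological_order <- function(dag) {
  nodes <- sort(dag$nodes)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(dag$edges$child)
  indeg[names(tab)] <- as.integer(tab)
  children <- split(dag$edges$child, dag$edges$parent)
  out <- character(0)
  avail <- nodes[indeg == 0L]
  while (length(avail)) {
    v <- avail[1L] # lexicographically smallest source
    avail <- avail[-1L]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(out) != length(nodes))
    tpb_error("invalid_structure", "graph contains a directed cycle")
  out
}

node_names <- function(p) sprintf("X%0*d", max(2L, nchar(p)), seq_len(p))

make_variables <- function(p, kind, discrete_fraction, levels_set) {
  nm <- node_names(p)
  kinds <- switch(kind,
    continuous = rep("continuous", p),
    discrete   = rep("discrete", p),
    mixed = {
      nd <- max(1L, round(p * discrete_fraction))
      k <- rep("continuous", p)
      k[sample.int(p, nd)] <- "discrete"
      k
    },
    tpb_error("invalid_argument", "kind must be continuous, discrete or mixed"))
  lev <- rep(NA_integer_, p)
  ndis <- sum(kinds == "discrete")
  if (ndis > 0L)
    lev[kinds == "discrete"] <-
      levels_set[sample.int(length(levels_set), ndis, replace = TRUE)]
  data.frame(name = nm, kind = kinds, levels = lev, stringsAsFactors = FALSE)
}

#' Generate a random typed DAG
#'
#' Draws a uniformly random topological order over `p` nodes and includes
#' each forward pair independently with probability `2 * mean_parents /
#' (p - 1)`, so the expected in-degree (before type constraints) equals
#' `mean_parents`.  In mixed graphs continuous-to-discrete edges are
#' forbidden, and discrete children keep at most `max_discrete_parents`
#' parents (a random subset is retained when the draw exceeds the cap),
#' since a discrete child's table size grows exponentially in its parent
#' count.
#'
#' @param p Number of nodes (>= 1).
#' @param mean_parents Target expected number of parents per node
#'   (0 <= `mean_parents` < `p`).
#' @param kind `"continuous"`, `"discrete"` or `"mixed"`.
#' @param discrete_fraction Fraction of discrete nodes when `kind = "mixed"`.
#' @param levels_set Integer set the per-node discrete level count is drawn
#'   from (uniformly).
#' @param max_discrete_parents In-degree cap for discrete children.
#' @param seed Optional integer seed; the same seed reproduces the graph
#'   bit-identically.
#' @return A [typed_dag()].
#' @export
#' @examples
#' g <- generate_random_dag(10, mean_parents = 1.5, seed = 1)
#' nrow(g$edges)
generate_random_dag <- function(p, mean_parents = 1.5, kind = "continuous",
                                discrete_fraction = 0.5, levels_set = 2:3,
                                max_discrete_parents = 3L, seed = NULL) {
  tpb_assert(is.numeric(p) && length(p) == 1L && p >= 1, "invalid_argument", "p must be >= 1")
  tpb_assert(mean_parents >= 0, "invalid_argument", "mean_parents must be >= 0")
  tpb_assert(mean_parents < p, "invalid_argument", "mean_parents must be < p")
  p <- as.integer(p)
  seed_if(seed)
  vars <- make_variables(p, kind, discrete_fraction, levels_set)
  ord <- sample.int(p) # position -> node index
  q <- if (p > 1L) min(1, 2 * mean_parents / (p - 1)) else 0
  edges <- NULL
  if (p > 1L && q > 0) {
    ij <- which(upper.tri(diag(p)), arr.ind = TRUE) # all forward position pairs
    keep <- stats::runif(nrow(ij)) < q
    ij <- ij[keep, , drop = FALSE]
    edges <- data.frame(parent = vars$name[ord[ij[, 1L]]],
                        child = vars$name[ord[ij[, 2L]]],
                        stringsAsFactors = FALSE)
    kindv <- stats::setNames(vars$kind, vars$name)
    # mixed constraint: never point a continuous parent at a discrete child
    drop <- kindv[edges$child] == "discrete" & kindv[edges$parent] == "continuous"
    edges <- edges[!drop, , drop = FALSE]
    # in-degree cap for discrete children
    for (ch in unique(edges$child[kindv[edges$child] == "discrete"])) {
      idx <- which(edges$child == ch)
      if (length(idx) > max_discrete_parents) {
        keep_idx <- sort(sample(idx, max_discrete_parents))
        edges <- edges[-setdiff(idx, keep_idx), , drop = FALSE]
      }
    }
  }
  typed_dag(vars, edges)
}

#' Generate a scale-free DAG by preferential attachment
#'
#' Nodes are added one at a time; each new node receives
#' `attachment_edges` incoming edges from existing nodes chosen with
#' probability proportional to their current degree plus one.  Orienting
#' every edge from older to newer node guarantees acyclicity while the
#' degree distribution develops the heavy tail characteristic of
#' scale-free networks.  Only continuous networks are supported: a
#' preferential-attachment hub would violate the bounded in-degree a
#' discrete child requires.
#'
#' @param p Number of nodes (>= 2).
#' @param attachment_edges Number of existing nodes each new node attaches
#'   to (>= 1; capped at the number of existing nodes early on).
#' @param kind Must be `"continuous"`; anything else errors.
#' @param seed Optional integer seed.
#' @return A [typed_dag()] with all-continuous nodes.
#' @export
generate_scale_free_dag <- function(p, attachment_edges = 1L, kind = "continuous",
                                    seed = NULL) {
  tpb_assert(is.numeric(p) && p >= 2, "invalid_argument", "p must be >= 2")
  tpb_assert(attachment_edges >= 1, "invalid_argument", "attachment_edges must be >= 1")
  if (!identical(kind, "continuous"))
    tpb_error("unsupported_combination",
              "scale-free topology is only available for continuous networks")
  p <- as.integer(p)
  seed_if(seed)
  nm <- node_names(p)
  deg <- numeric(p)
  par_idx <- integer(0)
  chi_idx <- integer(0)
  for (t in 2:p) {
    m <- min(as.integer(attachment_edges), t - 1L)
    existing <- seq_len(t - 1L)
    targets <- if (length(existing) == 1L) existing else
      sample(existing, m, prob = deg[existing] + 1)
    par_idx <- c(par_idx, targets)
    chi_idx <- c(chi_idx, rep.int(t, m))
    deg[targets] <- deg[targets] + 1
    deg[t] <- deg[t] + m
  }
  vars <- data.frame(name = nm, kind = "continuous", levels = NA_integer_,
                     stringsAsFactors = FALSE)
  typed_dag(vars, data.frame(parent = nm[par_idx], child = nm[chi_idx],
                             stringsAsFactors = FALSE))
}
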