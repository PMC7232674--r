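# The two-phase structure learner.
# Phase 1 (enumerate_families): for every node, exhaustively score all
#   type-admissible parent subsets up to the in-degree cap and keep a ranked
#   list of the K best families (the empty family is always retained, so any
#   cycle can ultimately be broken).
# Phase 2 (assemble_*): combine one family per node into an acyclic graph
#   maximizing the global BIC — greedily by cheapest cycle repair, or exactly
#   by subset dynamic programming at small node counts.
# A classic hill-climbing learner over single-edge moves is included as the
# in-package baseline.

#' Structure-search configuration
#'
#' @param max_parents In-degree cap for parent-set enumeration (default 4,
#'   keeping exhaustive enumeration affordable at p = 50).
#' @param candidates_per_node Number of ranked families kept per node
#'   (default 20); cycle repair rarely descends past a handful.
#' @param assembler `"auto"` (default: exact dynamic programming up to 20
#'   nodes, greedy repair-and-ascent beyond), `"greedy_repair"` or
#'   `"exact_dp"`.
#' @param seed Integer seed driving the assembler's restart orders; a fixed
#'   `(data, config, seed)` triple always reproduces the same network.
#' @param subset_budget Maximum number of parent subsets enumerated
#'   exhaustively per node before staged enumeration kicks in.
#' @param alpha Dirichlet pseudo-count for discrete family scores.
#' @param restarts Number of seeded random-order restarts of the greedy
#'   assembler's ascent (default 10).
#' @return Object of class `search_config`.
#' @export
search_config <- function(max_parents = 4L, candidates_per_node = 20L,
                          assembler = c("auto", "greedy_repair", "exact_dp"),
                          seed = 0L, subset_budget = 100000L, alpha = 1,
                          restarts = 50L) {
  assembler <- match.arg(assembler)
  tpb_assert(max_parents >= 1, "invalid_argument", "max_parents must be >= 1")
  tpb_assert(candidates_per_node >= 1, "invalid_argument", "candidates_per_node must be >= 1")
  structure(list(max_parents = as.integer(max_parents),
                 candidates_per_node = as.integer(candidates_per_node),
                 assembler = assembler, seed = as.integer(seed),
                 subset_budget = as.integer(subset_budget), alpha = alpha,
                 restarts = as.integer(restarts)),
            class = "search_config")
}

# fast Gaussian family BIC straight from the Gram matrix; NA signals a
# rank-deficient design (caller falls back to the full scorer), +Inf a
# degenerate zero-variance fit
fast_gauss_bic <- function(ctx, yi, pidx) {
  idx <- c(1L, pidx)
  ch <- tryCatch(chol(ctx$G[idx, idx, drop = FALSE]), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  gy <- ctx$G[idx, yi]
  b <- backsolve(ch, backsolve(ch, gy, transpose = TRUE))
  n <- ctx$n
  sigma2 <- (ctx$G[yi, yi] - sum(b * gy)) / n
  if (sigma2 < 1e-12 * max(1, ctx$G[yi, yi] / n)) return(Inf)
  gaussian_loglik(n, sigma2) - (length(pidx) + 2L) / 2 * log(n)
}

subset_key <- function(s) paste(s, collapse = ",")

# score one candidate parent set, returning its bic only (fast paths where
# possible); Inf marks a degenerate family to be excluded from the ranking
score_subset_bic <- function(ctx, child, s, alpha, pure_gauss, yi) {
  if (pure_gauss)
    return({
      b <- fast_gauss_bic(ctx, yi, 1L + match(s, ctx$cont))
      if (is.na(b)) score_family(ctx, child, s, alpha)$bic else b
    })
  fs <- score_family(ctx, child, s, alpha)
  if (fs$degenerate) Inf else fs$bic
}

#' Enumerate and rank candidate parent families for one node
#'
#' Phase 1 of the learner: scores every type-admissible parent subset of
#' size up to `max_parents` (discrete children only consider discrete
#' candidates) and returns the `candidates_per_node` best families, ranked
#' by BIC with ties broken by smaller parent set and then lexicographic
#' parent names.  The empty-parent family is always present in the ranking.
#' When the number of subsets exceeds `subset_budget` the enumeration is
#' staged: all subsets of size <= 2 are scored, then only the current top
#' families are extended one parent at a time.
#'
#' @param data Data frame or [score_context()].
#' @param child Child column name.
#' @param config A [search_config()].
#' @return Object of class `family_candidates` with elements `child`,
#'   `ranked` (list of `family_score`), `staged` and `n_scored`.
#' @export
enumerate_families <- function(data, child, config = search_config()) {
  ctx <- score_context(data)
  tpb_assert(child %in% ctx$names, "invalid_argument", "unknown child column")
  cand <- setdiff(ctx$names, child)
  if (ctx$kind[[child]] == "discrete") cand <- cand[ctx$kind[cand] == "discrete"]
  cand <- sort(cand)
  mp <- min(config$max_parents, length(cand))
  if (ctx$kind[[child]] == "continuous") mp <- min(mp, ctx$n - 3L)
  mp <- max(mp, 0L)
  pure_gauss <- ctx$kind[[child]] == "continuous" &&
    all(ctx$kind[cand] == "continuous")
  yi <- if (child %in% ctx$cont) 1L + match(child, ctx$cont) else NA_integer_

  subs <- list()
  bics <- numeric(0)
  add_subsets <- function(sets) {
    b <- vapply(sets, function(s)
      score_subset_bic(ctx, child, s, config$alpha, pure_gauss, yi), 0)
    subs <<- c(subs, sets)
    bics <<- c(bics, b)
  }
  total <- sum(choose(length(cand), 0:mp))
  staged <- total > config$subset_budget
  if (!staged) {
    for (sz in 0:mp) {
      sets <- if (sz == 0L) list(character(0)) else
        apply(utils::combn(cand, sz), 2L, identity, simplify = FALSE)
      add_subsets(sets)
    }
  } else {
    for (sz in 0:min(2L, mp)) {
      sets <- if (sz == 0L) list(character(0)) else
        apply(utils::combn(cand, sz), 2L, identity, simplify = FALSE)
      add_subsets(sets)
    }
    K <- config$candidates_per_node
    if (mp > 2L) {
      seen <- new.env(parent = emptyenv())
      for (s in subs) assign(paste0("s:", subset_key(s)), TRUE, envir = seen)
      for (sz in 3:mp) {
        ord <- rank_families(bics, subs)
        beam <- subs[ord[seq_len(min(K, length(ord)))]]
        beam <- beam[lengths(beam) == sz - 1L]
        if (!length(beam)) break
        ext <- list()
        for (s in beam) for (u in setdiff(cand, s)) {
          ns <- sort(c(s, u))
          key <- paste0("s:", subset_key(ns))
          if (is.null(seen[[key]])) {
            assign(key, TRUE, envir = seen)
            ext <- c(ext, list(ns))
          }
        }
        if (length(ext)) add_subsets(ext)
      }
    }
  }

  ord <- rank_families(bics, subs)
  keep <- ord[seq_len(min(config$candidates_per_node, length(ord)))]
  if (!any(lengths(subs[keep]) == 0L)) {
    empty_pos <- which(lengths(subs) == 0L)[1L]
    keep <- c(keep, empty_pos) # the empty family always survives
  }
  ranked <- lapply(subs[keep], function(s) cached_score(ctx, child, s, config$alpha))
  out <- structure(list(child = child, ranked = ranked, staged = staged,
                        n_scored = length(bics),
                        child_kind = ctx$kind[[child]],
                        child_levels = ctx$levels[[child]]),
                   class = "family_candidates")
  # full scored table, kept for the assembler's ascent sweeps; degenerate
  # families carry -Inf so an ordinary maximum never selects them
  tab_bics <- bics
  tab_bics[!is.finite(tab_bics)] <- -Inf
  attr(out, "subset_table") <- list(subsets = subs, bics = tab_bics, ord = ord)
  out
}

# deterministic ranking: bic desc, then fewer parents, then lexicographic
# parent-name key; degenerate (+Inf) and failed families are dropped
rank_families <- function(bics, subs) {
  ok <- is.finite(bics) | lengths(subs) == 0L
  idx <- which(ok)
  np <- lengths(subs[idx])
  key <- vapply(subs[idx], subset_key, "")
  idx[order(-bics[idx], np, key, method = "radix")]
}

#' @export
print.family_candidates <- function(x, ...) {
  cat(sprintf("family_candidates for %s: %d ranked (of %d scored)%s\n",
              x$child, length(x$ranked), x$n_scored,
              if (isTRUE(x$staged)) " [staged]" else ""))
  invisible(x)
}

dag_from_parent_sets <- function(cands, parent_sets) {
  nodes <- names(cands)
  vars <- data.frame(name = nodes,
                     kind = vapply(cands, function(c) c$child_kind, ""),
                     levels = vapply(cands, function(c) c$child_levels, 1L),
                     stringsAsFactors = FALSE)
  el <- do.call(rbind, lapply(nodes, function(v) {
    pa <- parent_sets[[v]]
    if (length(pa)) data.frame(parent = pa, child = v, stringsAsFactors = FALSE)
  }))
  typed_dag(vars, el)
}

dag_from_candidates <- function(cands, sel) {
  ps <- lapply(names(cands), function(v) cands[[v]]$ranked[[sel[[v]]]]$parents)
  names(ps) <- names(cands)
  dag_from_parent_sets(cands, ps)
}

selection_bic <- function(cands, sel)
  sum(vapply(names(cands), function(v) cands[[v]]$ranked[[sel[[v]]]]$bic, 0))

# first cycle found by lexicographic depth-first search over parent->child
# edges; NULL when the graph is acyclic
find_cycle <- function(nodes, parent_sets) {
  children <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) for (u in parent_sets[[v]]) children[[u]] <- c(children[[u]], v)
  children <- lapply(children, sort)
  color <- stats::setNames(integer(length(nodes)), nodes)
  stack <- character(0)
  cycle <- NULL
  visit <- function(v) {
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in children[[v]]) {
      if (!is.null(cycle)) return()
      if (color[[w]] == 1L) {
        i <- match(w, stack)
        cycle <<- stack[i:length(stack)]
        return()
      }
      if (color[[w]] == 0L) visit(w)
    }
    color[v] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in nodes) {
    if (color[[v]] == 0L) visit(v)
    if (!is.null(cycle)) break
  }
  cycle
}

# descendants of every node under the given parent sets (children BFS)
descendants_of <- function(nodes, parent_sets, v) {
  children <- stats::setNames(vector("list", length(nodes)), nodes)
  for (w in nodes) for (u in parent_sets[[w]]) children[[u]] <- c(children[[u]], w)
  out <- character(0)
  queue <- children[[v]]
  while (length(queue)) {
    w <- queue[1L]
    queue <- queue[-1L]
    if (w %in% out) next
    out <- c(out, w)
    queue <- c(queue, children[[w]])
  }
  out
}

# 0/1 membership matrix of the scored subsets over the node set
subset_membership <- function(subsets, nodes) {
  M <- matrix(0, length(subsets), length(nodes), dimnames = list(NULL, nodes))
  for (i in seq_along(subsets)) if (length(subsets[[i]])) M[i, subsets[[i]]] <- 1
  M
}

# best-ranked scored family for `v` whose parents avoid `forbidden` (and,
# if `must_have` is given, contain it); returns NULL if none improves -Inf
best_allowed_family <- function(tab, M, ord, forbidden, must_have = NULL) {
  bad <- if (length(forbidden)) M[, forbidden, drop = FALSE] %*% rep(1, length(forbidden)) > 0
         else rep(FALSE, nrow(M))
  if (!is.null(must_have)) bad <- bad | M[, must_have] == 0
  for (i in ord) if (!bad[i]) return(list(idx = i, bic = tab$bics[i],
                                          parents = tab$subsets[[i]]))
  NULL
}

#' Assemble families into an acyclic network by cycle repair and BIC ascent
#'
#' Phase 2 of the learner.  Starts from every node's top-ranked family
#' and, while the union contains a directed cycle, repairs the first cycle
#' found by demoting the cycle node whose demotion — to its next-ranked
#' family that drops the offending cycle parent — costs the least global
#' BIC (ties broken by node name).  Because every ranked list ends at the
#' empty family, each repair strictly advances one node down a finite list
#' and this phase terminates in at most `p * K` repairs with an acyclic
#' graph.  The repaired graph is then improved by monotone coordinate
#' ascent on the global BIC over the full table of families scored in
#' phase 1: node sweeps re-select each node's best family among its
#' non-descendants, and edge-reversal sweeps re-orient single edges when
#' the paired family change improves the score.  Every accepted move
#' strictly increases the global BIC, so the ascent terminates.
#'
#' @param candidates List of [enumerate_families()] results, one per node
#'   (named by child, or names are taken from the elements).
#' @param config A [search_config()].
#' @return List with `dag` (a [typed_dag()]), `global_bic`, `repairs`
#'   (number of cycle-repair demotions), `sweeps` (ascent sweeps run) and
#'   `selection` (final parent set per node).
#' @export
assemble_greedy <- function(candidates, config = search_config()) {
  names(candidates) <- vapply(candidates, function(c) c$child, "")
  candidates <- candidates[order(names(candidates))]
  nodes <- names(candidates)
  sel <- stats::setNames(rep.int(1L, length(nodes)), nodes)
  repairs <- 0L
  repeat {
    parent_sets <- lapply(nodes, function(v) candidates[[v]]$ranked[[sel[[v]]]]$parents)
    names(parent_sets) <- nodes
    cyc <- find_cycle(nodes, parent_sets)
    if (is.null(cyc)) break
    best <- NULL
    for (i in seq_along(cyc)) {
      v <- cyc[i]
      pred <- cyc[if (i == 1L) length(cyc) else i - 1L] # v's parent on the cycle
      rl <- candidates[[v]]$ranked
      j <- sel[[v]] + 1L
      while (j <= length(rl) && pred %in% rl[[j]]$parents) j <- j + 1L
      if (j > length(rl)) next
      cost <- rl[[sel[[v]]]]$bic - rl[[j]]$bic
      if (is.null(best) || cost < best$cost - 1e-12 ||
          (abs(cost - best$cost) <= 1e-12 && v < best$v))
        best <- list(v = v, j = j, cost = cost)
    }
    sel[[best$v]] <- best$j
    repairs <- repairs + 1L
  }
  parent_sets <- lapply(nodes, function(v) candidates[[v]]$ranked[[sel[[v]]]]$parents)
  names(parent_sets) <- nodes
  cur <- stats::setNames(
    vapply(nodes, function(v) candidates[[v]]$ranked[[sel[[v]]]]$bic, 0), nodes)

  tabs <- lapply(candidates, function(cnd) {
    tab <- attr(cnd, "subset_table")
    if (is.null(tab)) { # fall back to the ranked list itself
      subs <- lapply(cnd$ranked, `[[`, "parents")
      tab <- list(subsets = subs,
                  bics = vapply(cnd$ranked, `[[`, 0, "bic"),
                  ord = seq_along(subs))
    }
    tab
  })
  Ms <- lapply(tabs, function(t) subset_membership(t$subsets, nodes))

  # ascent run 1: polish the repaired assignment
  st <- polish_sweeps(nodes, tabs, Ms, parent_sets, cur)
  best <- st
  # iterated local search over topological orders: ascend from the
  # incumbent's (perturbed) order, with occasional fresh random orders
  if (config$restarts > 0L && length(nodes) > 1L) {
    seed_if(derive_seed(config$seed, 97L))
    best_o <- topological_order(dag_from_parent_sets(candidates, best$parent_sets))
    for (r in seq_len(config$restarts)) {
      o <- if (r == 1L) best_o
      else if (r %% 5L == 0L) sample(nodes)
      else perturb_order(best_o)
      ores <- order_ascent(nodes, tabs, Ms, o)
      st <- polish_sweeps(nodes, tabs, Ms, ores$parent_sets, ores$bics)
      if (sum(st$cur) > sum(best$cur) + 1e-9) {
        best <- st
        best_o <- topological_order(dag_from_parent_sets(candidates, best$parent_sets))
      }
    }
  }
  list(dag = dag_from_parent_sets(candidates, best$parent_sets),
       global_bic = sum(best$cur), repairs = repairs,
       sweeps = best$sweeps, selection = best$parent_sets)
}

# monotone coordinate ascent over the scored family tables: node sweeps
# (re-select each node's best family among its non-descendants) alternated
# with edge-reversal sweeps, until neither improves the global BIC
polish_sweeps <- function(nodes, tabs, Ms, parent_sets, cur) {
  sweeps <- 0L
  repeat {
    improved <- FALSE
    for (v in nodes) {
      forbidden <- c(v, descendants_of(nodes, parent_sets, v))
      b <- best_allowed_family(tabs[[v]], Ms[[v]], tabs[[v]]$ord, forbidden)
      if (!is.null(b) && b$bic > cur[[v]] + 1e-9) {
        parent_sets[[v]] <- b$parents
        cur[[v]] <- b$bic
        improved <- TRUE
      }
    }
    for (v in nodes) for (u in nodes) {
      if (!(u %in% parent_sets[[v]])) next
      tmp <- parent_sets
      tmp[[v]] <- setdiff(parent_sets[[v]], u)
      if (has_path(nodes, tmp, u, v)) next # another path keeps u above v
      bv <- best_allowed_family(tabs[[v]], Ms[[v]], tabs[[v]]$ord,
                                c(v, u, descendants_of(nodes, tmp, v)))
      if (is.null(bv)) next
      tmp2 <- tmp
      tmp2[[v]] <- bv$parents
      bu <- best_allowed_family(tabs[[u]], Ms[[u]], tabs[[u]]$ord,
                                c(u, descendants_of(nodes, tmp2, u)),
                                must_have = v)
      if (is.null(bu)) next
      delta <- (bv$bic - cur[[v]]) + (bu$bic - cur[[u]])
      if (delta > 1e-9) {
        parent_sets[[v]] <- bv$parents
        parent_sets[[u]] <- bu$parents
        cur[[v]] <- bv$bic
        cur[[u]] <- bu$bic
        improved <- TRUE
      }
    }
    sweeps <- sweeps + 1L
    if (!improved) break
  }
  list(parent_sets = parent_sets, cur = cur, sweeps = sweeps)
}

# random segment reversal: the standard order perturbation for iterated
# local search
perturb_order <- function(o) {
  p <- length(o)
  if (p < 3L) return(sample(o))
  i <- sample.int(p - 1L, 1L)
  j <- min(p, i + 1L + sample.int(max(1L, p %/% 2L), 1L))
  o[i:j] <- rev(o[i:j])
  o
}

# greedy ascent over topological orders: the score of an order is the sum
# over nodes of the best scored family drawn from the node's order
# predecessors; adjacent transpositions are accepted while they improve it
order_ascent <- function(nodes, tabs, Ms, o) {
  g <- function(v, preds) {
    best_allowed_family(tabs[[v]], Ms[[v]], tabs[[v]]$ord, setdiff(nodes, preds))
  }
  p <- length(o)
  fams <- vector("list", p)
  names(fams) <- o
  for (i in seq_len(p)) fams[[o[i]]] <- g(o[i], o[seq_len(i - 1L)])
  repeat {
    changed <- FALSE
    for (i in seq_len(p - 1L)) {
      a <- o[i]
      b <- o[i + 1L]
      fb <- if (a %in% fams[[b]]$parents)
        g(b, setdiff(o[seq_len(i)], a)) else fams[[b]]
      fa <- g(a, c(o[seq_len(i - 1L)], b))
      delta <- (fa$bic + fb$bic) - (fams[[a]]$bic + fams[[b]]$bic)
      if (delta > 1e-9) {
        o[i] <- b
        o[i + 1L] <- a
        fams[[a]] <- fa
        fams[[b]] <- fb
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ps <- lapply(fams, function(f) f$parents)
  list(order = o, parent_sets = ps[sort(names(ps))],
       bics = vapply(fams, function(f) f$bic, 0)[sort(names(ps))],
       total = sum(vapply(fams, function(f) f$bic, 0)))
}

#' Exact acyclic assembly by subset dynamic programming
#'
#' Finds the acyclic assignment of one scored family per node that
#' maximizes the summed BIC via the classic order-based recursion
#' `best(S) = max over sinks v in S of best(S \ v) + best family of v with
#' parents in S \ v`, with the per-node "best family inside a set" table
#' computed by a subset zeta transform (compiled kernel).  Families are
#' drawn from the full table scored in phase 1 when available (as the
#' greedy assembler's ascent does), otherwise from the ranked candidate
#' list.  Exponential in the node count; limited to p <= 20.
#'
#' @inheritParams assemble_greedy
#' @return As [assemble_greedy()] (with `repairs = NA`).
#' @export
assemble_exact_dp <- function(candidates, config = search_config()) {
  names(candidates) <- vapply(candidates, function(c) c$child, "")
  candidates <- candidates[order(names(candidates))]
  nodes <- names(candidates)
  p <- length(nodes)
  if (p > 20L) tpb_error("size_limit", "exact assembly is limited to p <= 20")
  fams <- lapply(candidates, function(cnd) {
    tab <- attr(cnd, "subset_table")
    if (!is.null(tab)) {
      ord <- tab$ord[is.finite(tab$bics[tab$ord])]
      list(subsets = tab$subsets[ord], bics = tab$bics[ord])
    } else {
      keep <- which(vapply(cnd$ranked, function(f) is.finite(f$bic), TRUE))
      list(subsets = lapply(cnd$ranked[keep], `[[`, "parents"),
           bics = vapply(cnd$ranked[keep], `[[`, 0, "bic"))
    }
  })
  masks <- lapply(fams, function(f)
    vapply(f$subsets, function(s)
      as.integer(sum(2^(match(s, nodes) - 1L))), 0L))
  res <- exact_dp_cpp(p, masks, lapply(fams, `[[`, "bics"))
  parent_sets <- lapply(seq_len(p), function(v)
    fams[[v]]$subsets[[res$selection[v]]])
  names(parent_sets) <- nodes
  list(dag = dag_from_parent_sets(candidates, parent_sets),
       global_bic = res$score, repairs = NA_integer_,
       selection = parent_sets)
}

#' Learn a Bayesian network structure by two-phase BIC search
#'
#' Runs [enumerate_families()] for every column of the data, then the
#' configured assembler, and reports the learned DAG with per-edge weights:
#' the fitted regression coefficient for a continuous parent of a
#' continuous child, and the family's BIC gain over the empty family for
#' edges involving discrete variables.
#'
#' @param data Data frame (numeric columns continuous, factor columns
#'   discrete) with at least 2 rows.
#' @param config A [search_config()].
#' @return Object of class `bn_learn` with elements `dag`, `global_bic`,
#'   `edges` (data frame `parent`, `child`, `weight`), `families_scored`,
#'   `repairs` and `config`.
#' @export
#' @examples
#' inst <- simulate_instance(sim_config(p = 5, n = 200, seed = 1))
#' fit <- learn(inst$data, search_config(max_parents = 2))
#' fit$edges
learn <- function(data, config = search_config()) {
  ctx <- score_context(data)
  tpb_assert(ctx$n >= 2, "invalid_argument", "need at least 2 rows")
  cands <- lapply(ctx$names, function(v) enumerate_families(ctx, v, config))
  names(cands) <- ctx$names
  assembler <- config$assembler
  if (assembler == "auto")
    assembler <- if (length(ctx$names) <= 20L) "exact_dp" else "greedy_repair"
  res <- switch(assembler,
                greedy_repair = assemble_greedy(cands, config),
                exact_dp = assemble_exact_dp(cands, config))
  dag <- res$dag
  edges <- dag$edges
  w <- numeric(nrow(edges))
  if (nrow(edges)) {
    for (v in unique(edges$child)) {
      fs <- cached_score(ctx, v, parents_of(dag, v), config$alpha)
      empty <- cached_score(ctx, v, character(0), config$alpha)
      idx <- which(edges$child == v)
      for (i in idx) {
        u <- edges$parent[i]
        w[i] <- if (ctx$kind[[v]] == "continuous" && ctx$kind[[u]] == "continuous")
          unname(fs$coefs[[u]]) else fs$bic - empty$bic
      }
    }
  }
  edges$weight <- w
  structure(list(dag = dag, global_bic = res$global_bic, edges = edges,
                 families_scored = sum(vapply(cands, function(c) c$n_scored, 0)),
                 repairs = res$repairs, config = config),
            class = "bn_learn")
}

#' @export
print.bn_learn <- function(x, ...) {
  cat(sprintf("bn_learn: %d edges, global BIC %.4f (%d families scored, %s)\n",
              nrow(x$edges), x$global_bic, x$families_scored,
              if (is.na(x$repairs)) "exact-DP assembly"
              else sprintf("%d cycle repairs", x$repairs)))
  invisible(x)
}

admissible_edge <- function(ctx, u, v) {
  !(ctx$kind[[v]] == "discrete" && ctx$kind[[u]] == "continuous")
}

# is there a directed path from -> to under the given parent sets?
has_path <- function(nodes, parent_sets, from, to) {
  children <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) for (u in parent_sets[[v]]) children[[u]] <- c(children[[u]], v)
  seen <- stats::setNames(logical(length(nodes)), nodes)
  queue <- from
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    if (v == to) return(TRUE)
    if (seen[[v]]) next
    seen[[v]] <- TRUE
    queue <- c(queue, children[[v]])
  }
  FALSE
}

#' Hill-climbing baseline learner
#'
#' Classic greedy search over single-edge moves (add, delete, reverse)
#' maximizing the global BIC gain, stopping when no move improves.  Moves
#' respect acyclicity, the discrete-parent constraint and the
#' `max_parents` cap; ties are broken by move type then lexicographic
#' edge, so the result is deterministic.
#'
#' @inheritParams learn
#' @return Object of class `bn_learn` (with `repairs = NA`).
#' @export
hill_climb_baseline <- function(data, config = search_config()) {
  ctx <- score_context(data)
  tpb_assert(ctx$n >= 2, "invalid_argument", "need at least 2 rows")
  nodes <- ctx$names
  pars <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  sc <- function(v, pa) {
    fs <- cached_score(ctx, v, pa, config$alpha)
    if (fs$degenerate && is.infinite(fs$bic)) -Inf else fs$bic
  }
  cur <- vapply(nodes, function(v) sc(v, character(0)), 0)
  move_rank <- c(add = 1L, del = 2L, rev = 3L)
  n_scored <- 0L
  repeat {
    best <- NULL
    take <- function(type, u, v, delta) {
      if (delta <= 1e-9) return()
      if (is.null(best) || delta > best$delta + 1e-12 ||
          (abs(delta - best$delta) <= 1e-12 &&
           (move_rank[[type]] < move_rank[[best$type]] ||
            (move_rank[[type]] == move_rank[[best$type]] &&
             paste(u, v) < paste(best$u, best$v)))))
        best <<- list(type = type, u = u, v = v, delta = delta)
    }
    for (v in nodes) for (u in nodes) {
      if (u == v) next
      pa <- pars[[v]]
      if (u %in% pa) {
        pa_del <- setdiff(pa, u)
        take("del", u, v, sc(v, pa_del) - cur[[v]])
        if (admissible_edge(ctx, v, u) &&
            length(pars[[u]]) < config$max_parents) {
          tmp <- pars
          tmp[[v]] <- pa_del
          if (!has_path(nodes, tmp, u, v)) {
            delta <- (sc(v, pa_del) - cur[[v]]) +
              (sc(u, sort(c(pars[[u]], v))) - cur[[u]])
            take("rev", u, v, delta)
          }
        }
      } else if (admissible_edge(ctx, u, v) &&
                 length(pa) < config$max_parents &&
                 !has_path(nodes, pars, v, u)) {
        take("add", u, v, sc(v, sort(c(pa, u))) - cur[[v]])
      }
    }
    if (is.null(best)) break
    if (best$type == "add") {
      pars[[best$v]] <- sort(c(pars[[best$v]], best$u))
    } else if (best$type == "del") {
      pars[[best$v]] <- setdiff(pars[[best$v]], best$u)
    } else {
      pars[[best$v]] <- setdiff(pars[[best$v]], best$u)
      pars[[best$u]] <- sort(c(pars[[best$u]], best$v))
    }
    for (v in nodes) cur[[v]] <- sc(v, pars[[v]])
  }
  vars <- data.frame(name = nodes, kind = ctx$kind[nodes],
                     levels = ctx$levels[nodes], stringsAsFactors = FALSE)
  el <- do.call(rbind, lapply(nodes, function(v) {
    if (length(pars[[v]])) data.frame(parent = pars[[v]], child = v,
                                      stringsAsFactors = FALSE)
  }))
  dag <- typed_dag(vars, el)
  edges <- dag$edges
  if (nrow(edges)) edges$weight <- rep(1, nrow(edges))
  else edges$weight <- numeric(0)
  structure(list(dag = dag, global_bic = sum(cur), edges = edges,
                 families_scored = length(ls(ctx$cache)),
                 repairs = NA_integer_, config = config),
            class = "bn_learn")
}
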