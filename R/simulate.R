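# Linear-SEM simulator: draws ground-truth parameterized networks and
# samples datasets from them by ancestral sampling, reproducing the
# benchmark's generative design:
#   * continuous child, continuous parents: X_i ~ N(sum_j beta_ji X_j, sigma_i^2)
#     with |beta| ~ N(2, 0.8) and a Bernoulli(0.5) sign, sigma_i^2 ~ N(1, 0.01)
#   * discrete child: multinomial CPT with enforced parent-child dependence
#   * continuous child with discrete parents: conditional-Gaussian
#     (per-configuration intercepts), marginally a Gaussian mixture

#' Simulation configuration
#'
#' Bundles every knob of one synthetic-network setting: network kind,
#' topology, node and sample size, and the parameter-generating
#' distributions.  The defaults are the benchmark's generative conditions;
#' `second_arg` selects whether the spread arguments (`beta_sd`,
#' `sigma2_sd`) are standard deviations (default) or variances.
#'
#' @param network_kind `"continuous"`, `"discrete"` or `"mixed"`.
#' @param topology `"random"` or `"scale_free"` (scale-free requires a
#'   continuous network).
#' @param p,n Node count and sample size.
#' @param seed Integer seed; drives topology, parameters, sampling and the
#'   column shuffle through independent derived streams.
#' @param mean_parents Expected in-degree of the random topology.
#' @param attachment_edges Attachment count for scale-free topology.
#' @param discrete_fraction,levels_set,max_discrete_parents Passed to
#'   [generate_random_dag()].
#' @param beta_mean,beta_sd Location/spread of the coefficient magnitude
#'   `|beta| ~ N(beta_mean, beta_sd)`.
#' @param sign_prob Probability that a coefficient is positive.
#' @param sigma2_mean,sigma2_sd Location/spread of the residual variance
#'   draw, truncated below at `1e-3`.
#' @param second_arg `"sd"` or `"var"`: how `beta_sd`/`sigma2_sd` are read.
#' @param shuffle_columns Shuffle the dataset's column order (on by
#'   default), so learners cannot exploit the ancestral variable order.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(network_kind = "continuous", topology = "random",
                       p = 20L, n = 1000L, seed = 1L,
                       mean_parents = 1.5, attachment_edges = 1L,
                       discrete_fraction = 0.5, levels_set = 2:3,
                       max_discrete_parents = 3L,
                       beta_mean = 2, beta_sd = 0.8, sign_prob = 0.5,
                       sigma2_mean = 1, sigma2_sd = 0.01,
                       second_arg = c("sd", "var"), shuffle_columns = TRUE) {
  second_arg <- match.arg(second_arg)
  tpb_assert(network_kind %in% c("continuous", "discrete", "mixed"),
             "invalid_argument", "unknown network_kind")
  tpb_assert(topology %in% c("random", "scale_free"), "invalid_argument", "unknown topology")
  if (topology == "scale_free" && network_kind != "continuous")
    tpb_error("unsupported_combination",
              "scale-free topology is only available for continuous networks")
  tpb_assert(p >= 1 && n >= 1, "invalid_argument", "p and n must be >= 1")
  tpb_assert(sign_prob >= 0 && sign_prob <= 1, "invalid_argument", "sign_prob in [0,1]")
  tpb_assert(beta_sd >= 0 && sigma2_sd >= 0, "invalid_argument", "spreads must be >= 0")
  structure(list(network_kind = network_kind, topology = topology,
                 p = as.integer(p), n = as.integer(n), seed = as.integer(seed),
                 mean_parents = mean_parents, attachment_edges = attachment_edges,
                 discrete_fraction = discrete_fraction, levels_set = levels_set,
                 max_discrete_parents = max_discrete_parents,
                 beta_mean = beta_mean, beta_sd = beta_sd, sign_prob = sign_prob,
                 sigma2_mean = sigma2_mean, sigma2_sd = sigma2_sd,
                 second_arg = second_arg, shuffle_columns = isTRUE(shuffle_columns)),
            class = "sim_config")
}

sd_of <- function(x, second_arg) if (second_arg == "var") sqrt(x) else x

draw_beta <- function(k, config) {
  if (k == 0L) return(numeric(0))
  b <- abs(stats::rnorm(k, config$beta_mean, sd_of(config$beta_sd, config$second_arg)))
  s <- ifelse(stats::runif(k) < config$sign_prob, 1, -1)
  s * b
}

draw_sigma2 <- function(k, config, floor = 1e-3) {
  if (k == 0L) return(numeric(0))
  s <- stats::rnorm(k, config$sigma2_mean, sd_of(config$sigma2_sd, config$second_arg))
  for (i in which(s < floor)) { # truncated-below draw; N(1, 0.01) ~never hits it
    for (tries in 1:100) {
      s[i] <- stats::rnorm(1, config$sigma2_mean, sd_of(config$sigma2_sd, config$second_arg))
      if (s[i] >= floor) break
    }
    if (s[i] < floor) s[i] <- floor
  }
  s
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# rows of a CPT that differ in exactly one parent's level
cpt_neighbor_pairs <- function(levels) {
  ncfg <- prod(levels)
  if (length(levels) == 0L || ncfg == 1L) return(matrix(integer(0), ncol = 2L))
  grid <- as.matrix(expand.grid(lapply(levels, seq_len)))
  pairs <- utils::combn(ncfg, 2L)
  diffs <- rowSums(grid[pairs[1L, ], , drop = FALSE] !=
                     grid[pairs[2L, ], , drop = FALSE])
  t(pairs[, diffs == 1L, drop = FALSE])
}

draw_cpt <- function(child_levels, parent_levels, min_tv = 0.1, max_iter = 1000L) {
  ncfg <- max(1L, prod(parent_levels))
  rdir <- function(k) { g <- stats::rgamma(child_levels * k, 1); m <- matrix(g, k); m / rowSums(m) }
  tab <- rdir(ncfg)
  nb <- cpt_neighbor_pairs(parent_levels)
  if (nrow(nb)) {
    # resample one offending row at a time until every neighbouring pair of
    # configurations moves the child distribution by TV >= min_tv
    for (iter in seq_len(max_iter)) {
      tv <- vapply(seq_len(nrow(nb)),
                   function(i) tv_distance(tab[nb[i, 1L], ], tab[nb[i, 2L], ]), 0)
      bad <- which(tv < min_tv)
      if (!length(bad)) break
      row <- nb[bad[1L], 1L + (stats::runif(1) < 0.5)]
      tab[row, ] <- rdir(1L)
      if (iter == max_iter)
        tpb_error("cpt_dependence_failure",
                  "could not satisfy the CPT dependence criterion")
    }
  }
  tab
}

#' Draw ground-truth parameters for a typed DAG
#'
#' Equips every node with a conditional distribution drawn from the
#' benchmark's generative scheme: coefficient magnitudes from
#' `N(beta_mean, beta_sd)` with a Bernoulli sign, residual variances from
#' `N(sigma2_mean, sigma2_sd)` truncated below at `1e-3`, Dirichlet(1) CPT
#' rows resampled until every pair of configurations differing in one
#' parent level is at total-variation distance >= 0.1 (so each parent
#' genuinely moves the child), and per-configuration intercepts for
#' conditional-Gaussian children.
#'
#' @param dag A [typed_dag()].
#' @param config A [sim_config()]; only the parameter fields are used.
#' @return A [parameterized_network()].
#' @export
draw_parameters <- function(dag, config = sim_config()) {
  seed_if(derive_seed(config$seed, 2L))
  cpds <- vector("list", length(dag$nodes))
  names(cpds) <- dag$nodes
  for (v in dag$nodes) {
    pa <- parents_of(dag, v)
    pk <- dag$kind[pa]
    if (dag$kind[[v]] == "discrete") {
      if (any(pk == "continuous"))
        tpb_error("invalid_structure", "discrete child with continuous parent")
      plev <- stats::setNames(dag$levels[pa], pa)
      cpds[[v]] <- multinomial_cpd(draw_cpt(dag$levels[[v]], plev), plev)
    } else if (!any(pk == "discrete")) {
      betas <- stats::setNames(draw_beta(length(pa), config), pa)
      cpds[[v]] <- lingauss_cpd(betas, intercept = 0,
                                sigma2 = draw_sigma2(1L, config))
    } else {
      dpa <- pa[pk == "discrete"]
      cpa <- pa[pk == "continuous"]
      dlev <- stats::setNames(dag$levels[dpa], dpa)
      cpds[[v]] <- cgauss_cpd(
        intercepts = draw_beta(prod(dlev), config),
        betas = stats::setNames(draw_beta(length(cpa), config), cpa),
        sigma2 = draw_sigma2(1L, config), dparent_levels = dlev)
    }
  }
  parameterized_network(dag, cpds)
}

#' Sample a dataset from a parameterized network
#'
#' Ancestral sampling in topological order: each continuous node is its
#' (configuration-specific) intercept plus the linear parent combination
#' plus `N(0, sigma2)` noise; each discrete node is drawn from the CPT row
#' of its realized parent configuration.
#'
#' @param network A [parameterized_network()].
#' @param n Number of rows (>= 1).
#' @param seed Optional seed.
#' @return A data frame with one column per node, in the dag's node order;
#'   discrete columns are factors with levels `1..L`.
#' @export
sample_dataset <- function(network, n, seed = NULL) {
  tpb_assert(n >= 1, "invalid_argument", "n must be >= 1")
  seed_if(seed)
  dag <- network$dag
  n <- as.integer(n)
  cols <- vector("list", length(dag$nodes))
  names(cols) <- dag$nodes
  for (v in topological_order(dag)) {
    cpd <- network$cpds[[v]]
    cols[[v]] <- switch(class(cpd)[1L],
      lingauss_cpd = {
        mu <- rep.int(cpd$intercept, n)
        for (u in cpd$parents) mu <- mu + cpd$betas[[u]] * cols[[u]]
        mu + stats::rnorm(n, 0, sqrt(cpd$sigma2))
      },
      cgauss_cpd = {
        codes <- vapply(cpd$dparents, function(u) as.integer(cols[[u]]),
                        integer(n))
        cfg <- config_index(cpd$dparent_levels, matrix(codes, ncol = length(cpd$dparents)))
        mu <- cpd$intercepts[cfg]
        for (u in cpd$cparents) mu <- mu + cpd$betas[[u]] * cols[[u]]
        mu + stats::rnorm(n, 0, sqrt(cpd$sigma2))
      },
      multinomial_cpd = {
        L <- ncol(cpd$table)
        if (length(cpd$parents) == 0L) {
          out <- sample.int(L, n, replace = TRUE, prob = cpd$table[1L, ])
        } else {
          codes <- vapply(cpd$parents, function(u) as.integer(cols[[u]]), integer(n))
          cfg <- config_index(cpd$parent_levels, matrix(codes, ncol = length(cpd$parents)))
          out <- integer(n)
          for (g in sort(unique(cfg))) {
            idx <- which(cfg == g)
            out[idx] <- sample.int(L, length(idx), replace = TRUE,
                                   prob = cpd$table[g, ])
          }
        }
        factor(out, levels = seq_len(L))
      })
  }
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Simulate one benchmark instance
#'
#' Composes topology generation, parameter drawing and ancestral sampling,
#' then (by default) applies a seeded permutation to the dataset's column
#' order so a learner can never read the generative variable ordering off
#' the file.  Everything is reproducible from the configuration alone.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_instance` with elements `truth`
#'   (a [parameterized_network()]), `data` (data frame, possibly
#'   column-shuffled), `column_permutation` (integer vector such that
#'   `data` is the unshuffled dataset's columns in that order) and
#'   `config`.
#' @export
#' @examples
#' inst <- simulate_instance(sim_config(p = 5, n = 20, seed = 1))
#' dim(inst$data)
simulate_instance <- function(config) {
  tpb_assert(inherits(config, "sim_config"), "invalid_argument", "config must be a sim_config")
  dag <- if (config$topology == "scale_free") {
    generate_scale_free_dag(config$p, config$attachment_edges,
                            seed = derive_seed(config$seed, 1L))
  } else {
    generate_random_dag(config$p, config$mean_parents, config$network_kind,
                        config$discrete_fraction, config$levels_set,
                        config$max_discrete_parents,
                        seed = derive_seed(config$seed, 1L))
  }
  truth <- draw_parameters(dag, config)
  data <- sample_dataset(truth, config$n, seed = derive_seed(config$seed, 3L))
  perm <- seq_len(config$p)
  if (config$shuffle_columns && config$p > 1L) {
    seed_if(derive_seed(config$seed, 4L))
    perm <- sample.int(config$p)
    data <- data[, perm, drop = FALSE]
  }
  structure(list(truth = truth, data = data, column_permutation = perm,
                 config = config),
            class = "sim_instance")
}

#' @export
print.sim_instance <- function(x, ...) {
  cat(sprintf("sim_instance: %s %s network, p=%d, n=%d, seed=%d\n",
              x$config$network_kind, x$config$topology, x$config$p,
              x$config$n, x$config$seed))
  invisible(x)
}

#' Expand a benchmark grid into replicate configurations
#'
#' Crosses network kinds, topologies, node sizes and sample sizes, skips
#' combinations the simulator does not support (scale-free with a
#' non-continuous kind), and replicates each remaining setting with
#' distinct seeds derived from `base_seed`.  The benchmark's own small
#' feature-space design — kinds continuous/discrete/mixed, topologies
#' random/scale-free, p in {10, 20, 50}, n in {50, 200, 1000} — yields
#' 36 settings.
#'
#' @param kinds,topologies,node_sizes,sample_sizes Nonempty vectors defining
#'   the cross product.
#' @param replicates Replicates per setting (0 gives an empty list).
#' @param base_seed Base seed for the derived per-replicate seeds.
#' @param ... Further arguments passed to [sim_config()] (e.g.
#'   `mean_parents`).
#' @return List of [sim_config()] objects, each with `$replicate` and
#'   `$setting` fields attached.
#' @export
benchmark_grid <- function(kinds = c("continuous", "discrete", "mixed"),
                           topologies = c("random", "scale_free"),
                           node_sizes = c(10L, 20L, 50L),
                           sample_sizes = c(50L, 200L, 1000L),
                           replicates = 1L, base_seed = 1L, ...) {
  tpb_assert(length(kinds) > 0 && length(topologies) > 0 &&
               length(node_sizes) > 0 && length(sample_sizes) > 0,
             "invalid_argument", "grid dimensions must be nonempty")
  out <- list()
  idx <- 0L
  setting <- 0L
  for (kind in kinds) for (topo in topologies) {
    if (topo == "scale_free" && kind != "continuous") next
    for (p in node_sizes) for (n in sample_sizes) {
      setting <- setting + 1L
      for (r in seq_len(replicates)) {
        idx <- idx + 1L
        cfg <- sim_config(network_kind = kind, topology = topo, p = p, n = n,
                          seed = derive_seed(base_seed, idx), ...)
        cfg$replicate <- r
        cfg$setting <- sprintf("%s_%s_p%d_n%d", kind, topo, p, n)
        out[[idx]] <- cfg
      }
    }
  }
  out
}
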