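# Conditional distributions attached to DAG nodes, and the factorized joint
# density they define.  Three families cover the supported network types:
#   * linear-Gaussian: continuous child, continuous parents
#   * multinomial CPT: discrete child, discrete parents
#   * conditional-Gaussian: continuous child, discrete (+ continuous) parents,
#     one regression intercept per discrete-parent configuration

#' Linear-Gaussian conditional distribution
#'
#' `X_child = intercept + sum_j beta_j X_j + e`, `e ~ N(0, sigma2)`.
#'
#' @param betas Named numeric vector of parent coefficients (may be empty).
#' @param intercept Scalar intercept.
#' @param sigma2 Residual variance, > 0.
#' @return Object of class `lingauss_cpd`.
#' @export
lingauss_cpd <- function(betas = numeric(0), intercept = 0, sigma2 = 1) {
  tpb_assert(sigma2 > 0, "invalid_argument", "sigma2 must be > 0")
  if (length(betas)) betas <- betas[order(names(betas))]
  structure(list(parents = names(betas) %||% character(0), betas = betas,
                 intercept = intercept, sigma2 = sigma2),
            class = "lingauss_cpd")
}

#' Multinomial conditional probability table
#'
#' One probability row per configuration of the (discrete) parents; rows are
#' indexed with the first parent (in sorted name order) varying fastest, as
#' in [config_index()].
#'
#' @param table Numeric matrix, `prod(parent_levels)` rows by child-level
#'   columns; each row sums to 1.
#' @param parent_levels Named integer vector of parent level counts, sorted
#'   by parent name (empty for a root node, giving a 1-row table).
#' @return Object of class `multinomial_cpd`.
#' @export
multinomial_cpd <- function(table, parent_levels = integer(0)) {
  table <- as.matrix(table)
  if (length(parent_levels)) parent_levels <- parent_levels[order(names(parent_levels))]
  tpb_assert(nrow(table) == max(1L, prod(parent_levels)),
             "invalid_argument", "table rows must match parent configurations")
  tpb_assert(all(table >= 0) && all(abs(rowSums(table) - 1) < 1e-9),
             "invalid_argument", "CPT rows must be probability vectors")
  structure(list(parents = names(parent_levels) %||% character(0),
                 parent_levels = parent_levels, table = table),
            class = "multinomial_cpd")
}

#' Conditional-Gaussian distribution
#'
#' Continuous child whose regression intercept varies with the configuration
#' of its discrete parents while slopes on continuous parents and the
#' residual variance are shared across configurations.  Marginally this is a
#' Gaussian mixture.
#'
#' @param intercepts Numeric vector, one per discrete-parent configuration
#'   (indexed as in [config_index()]).
#' @param betas Named numeric coefficients on the continuous parents.
#' @param sigma2 Shared residual variance, > 0.
#' @param dparent_levels Named integer vector of discrete-parent level
#'   counts, sorted by name.
#' @return Object of class `cgauss_cpd`.
#' @export
cgauss_cpd <- function(intercepts, betas = numeric(0), sigma2 = 1,
                       dparent_levels = integer(0)) {
  tpb_assert(sigma2 > 0, "invalid_argument", "sigma2 must be > 0")
  tpb_assert(length(dparent_levels) >= 1, "invalid_argument",
             "cgauss_cpd needs at least one discrete parent")
  dparent_levels <- dparent_levels[order(names(dparent_levels))]
  tpb_assert(length(intercepts) == prod(dparent_levels),
             "invalid_argument", "one intercept per discrete-parent configuration")
  betas <- if (length(betas)) betas[order(names(betas))] else numeric(0)
  structure(list(parents = sort(c(names(dparent_levels), names(betas))),
                 dparents = names(dparent_levels), dparent_levels = dparent_levels,
                 cparents = names(betas) %||% character(0),
                 intercepts = intercepts, betas = betas, sigma2 = sigma2),
            class = "cgauss_cpd")
}

#' Row index of a discrete-parent configuration
#'
#' Mixed-radix indexing with the first parent (sorted by name) varying
#' fastest: levels `(l1, l2, ...)` map to
#' `1 + (l1-1) + L1*(l2-1) + L1*L2*(l3-1) + ...`.
#'
#' @param levels Integer vector of level counts per parent.
#' @param values Integer matrix or vector of level codes (1-based), one
#'   column per parent.
#' @return Integer configuration indices.
#' @export
config_index <- function(levels, values) {
  if (length(levels) == 0L) return(rep.int(1L, max(1L, NROW(values))))
  values <- if (is.matrix(values)) values else matrix(values, ncol = length(levels))
  stride <- cumprod(c(1L, levels[-length(levels)]))
  as.integer(1 + (values - 1) %*% stride)
}

#' Parameterized Bayesian network
#'
#' Couples a [typed_dag()] with one conditional distribution per node and
#' checks that each distribution's parent set matches the graph.
#'
#' @param dag A [typed_dag()].
#' @param cpds Named list, one cpd per node.
#' @return Object of class `param_bn` with elements `dag` and `cpds`.
#' @export
parameterized_network <- function(dag, cpds) {
  tpb_assert(setequal(names(cpds), dag$nodes), "invalid_argument",
             "cpds must cover exactly the dag nodes")
  for (v in dag$nodes) {
    pa <- parents_of(dag, v)
    tpb_assert(identical(sort(cpds[[v]]$parents), pa), "invalid_structure",
               sprintf("cpd parents for %s do not match the dag", v))
  }
  structure(list(dag = dag, cpds = cpds), class = "param_bn")
}

#' @export
print.param_bn <- function(x, ...) {
  cat("param_bn over "); print(x$dag); invisible(x)
}

sample_value <- function(x) {
  if (is.factor(x)) as.integer(x) else as.numeric(x)
}

#' Log joint density of one observation
#'
#' Evaluates `sum_i log P(x_i | parents(x_i))` under the network's
#' conditional distributions, i.e. the factorized joint of a Bayesian
#' network.  Discrete values are 1-based level codes (factors are accepted).
#'
#' @param network A [parameterized_network()].
#' @param sample Named list or one-row data frame with a value per node.
#' @return The log joint density (a scalar).
#' @export
log_joint <- function(network, sample) {
  dag <- network$dag
  sample <- as.list(sample)
  tpb_assert(all(dag$nodes %in% names(sample)), "invalid_argument",
             "sample must provide a value for every node")
  val <- lapply(sample, sample_value)
  total <- 0
  for (v in dag$nodes) {
    cpd <- network$cpds[[v]]
    x <- val[[v]]
    if (dag$kind[[v]] == "discrete") {
      if (is.na(x) || x < 1L || x > dag$levels[[v]] || x != round(x))
        tpb_error("invalid_value", sprintf("value for %s outside declared levels", v))
    }
    total <- total + switch(class(cpd)[1L],
      lingauss_cpd = {
        mu <- cpd$intercept + sum(cpd$betas * unlist(val[cpd$parents]))
        stats::dnorm(x, mu, sqrt(cpd$sigma2), log = TRUE)
      },
      multinomial_cpd = {
        pv <- unlist(val[cpd$parents])
        if (length(pv) && any(pv < 1L | pv > cpd$parent_levels))
          tpb_error("invalid_value", sprintf("parent value for %s outside levels", v))
        log(cpd$table[config_index(cpd$parent_levels, pv), x])
      },
      cgauss_cpd = {
        cfg <- config_index(cpd$dparent_levels, unlist(val[cpd$dparents]))
        mu <- cpd$intercepts[cfg] +
          if (length(cpd$betas)) sum(cpd$betas * unlist(val[cpd$cparents])) else 0
        stats::dnorm(x, mu, sqrt(cpd$sigma2), log = TRUE)
      },
      tpb_error("invalid_argument", "unknown cpd class"))
  }
  total
}
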