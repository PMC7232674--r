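# Decomposable BIC family scores.  The score of a DAG is the sum over nodes
# of local family scores bic = loglik - (k/2) * log(n) (maximized-score
# convention), so structure search only ever touches (child, parent-set)
# units.  Gaussian families are scored from a precomputed Gram matrix of the
# continuous columns, which makes a family score O(|parents|^3) independent
# of the sample size — the workhorse behind exhaustive parent-set
# enumeration.

#' Build a scoring context for a dataset
#'
#' Validates the dataset (numeric columns are continuous, factor columns
#' are discrete), reorders columns by name so every downstream computation
#' is invariant to the column order on disk, precomputes the Gram matrix
#' `[1, X]' [1, X]` of the continuous block, and attaches a family-score
#' cache.
#'
#' @param data Data frame (or an existing `score_context`, returned as-is).
#' @return Object of class `score_context`.
#' @export
score_context <- function(data) {
  if (inherits(data, "score_context")) return(data)
  tpb_assert(is.data.frame(data) && nrow(data) >= 1, "invalid_argument",
             "data must be a data frame with at least one row")
  nm <- sort(names(data))
  data <- data[, nm, drop = FALSE]
  kind <- vapply(data, function(x) if (is.factor(x)) "discrete" else "continuous", "")
  tpb_assert(all(vapply(data, function(x) is.factor(x) || is.numeric(x), TRUE)),
             "invalid_argument", "columns must be numeric (continuous) or factor (discrete)")
  tpb_assert(!anyNA(data), "parse_error", "missing values are not supported")
  cont <- nm[kind == "continuous"]
  disc <- nm[kind == "discrete"]
  Xc <- if (length(cont)) as.matrix(data[cont]) else matrix(0, nrow(data), 0)
  A <- cbind(`(Intercept)` = 1, Xc)
  G <- crossprod(A)
  D <- if (length(disc)) {
    vapply(disc, function(v) as.integer(data[[v]]), integer(nrow(data)))
  } else matrix(integer(0), nrow(data), 0)
  levels_ <- stats::setNames(rep(NA_integer_, length(nm)), nm)
  for (v in disc) levels_[v] <- nlevels(data[[v]])
  structure(list(data = data, n = nrow(data), names = nm, kind = kind,
                 levels = levels_, cont = cont, disc = disc,
                 Xc = Xc, G = G, D = D, cache = new.env(parent = emptyenv())),
            class = "score_context")
}

new_family_score <- function(child, parents, bic, loglik, k, n,
                             degenerate = FALSE, flag = NULL, coefs = NULL) {
  structure(list(child = child, parents = sort(parents), bic = bic,
                 loglik = loglik, k = k, n = n, degenerate = degenerate,
                 flag = flag, coefs = coefs),
            class = "family_score")
}

#' @export
print.family_score <- function(x, ...) {
  cat(sprintf("family_score: %s | {%s}  bic=%.4f  loglik=%.4f  k=%d  n=%d%s\n",
              x$child, paste(x$parents, collapse = ","), x$bic, x$loglik,
              x$k, x$n, if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

gaussian_loglik <- function(n, sigma2) -n / 2 * (log(2 * pi * sigma2) + 1)

#' BIC score of a linear-Gaussian family
#'
#' Fits the least-squares regression of a continuous child on its
#' (continuous) parents with an intercept, evaluates the Gaussian
#' log-likelihood at the MLE variance `RSS/n`, and penalizes
#' `k = |parents| + 2` free parameters (coefficients, intercept, variance):
#' `bic = loglik - (k/2) log(n)`.  A rank-deficient design is fit by
#' pseudoinverse and flagged; a zero residual variance is flagged
#' degenerate with a `+Inf` sentinel that structure search excludes.
#'
#' @param data Data frame or [score_context()].
#' @param child Continuous child column name.
#' @param parents Character vector of continuous parent names (may be
#'   empty).
#' @return A `family_score` with fields `child`, `parents`, `bic`,
#'   `loglik`, `k`, `n`, `degenerate` and the fitted `coefs`.
#' @export
#' @examples
#' d <- data.frame(x = c(0, 1, 2, 3, 4), y = c(0.1, 2.1, 3.9, 6.2, 7.9))
#' score_gaussian_family(d, "y", "x")$bic
score_gaussian_family <- function(data, child, parents = character(0)) {
  ctx <- score_context(data)
  parents <- sort(as.character(parents))
  tpb_assert(child %in% ctx$cont, "invalid_argument", "child must be a continuous column")
  tpb_assert(all(parents %in% ctx$cont), "invalid_argument",
             "score_gaussian_family needs continuous parents")
  if (ctx$n <= length(parents) + 2L)
    tpb_error("insufficient_data", "need n > |parents| + 2 for a Gaussian family")
  yi <- 1L + match(child, ctx$cont)
  idx <- c(1L, 1L + match(parents, ctx$cont))
  Gs <- ctx$G[idx, idx, drop = FALSE]
  gy <- ctx$G[idx, yi]
  flag <- NULL
  b <- tryCatch({
    ch <- chol(Gs)
    backsolve(ch, backsolve(ch, gy, transpose = TRUE))
  }, error = function(e) {
    flag <<- "rank_deficient"
    drop(MASS::ginv(Gs) %*% gy)
  })
  rss <- max(ctx$G[yi, yi] - sum(b * gy), 0)
  n <- ctx$n
  sigma2 <- rss / n
  k <- length(parents) + 2L
  scale <- max(1, ctx$G[yi, yi] / n)
  coefs <- stats::setNames(b, c("(Intercept)", parents))
  if (sigma2 < 1e-12 * scale) {
    if (length(parents) == 0L) {
      # constant column: floor the variance so the mandatory empty family
      # stays finite, but keep the flag
      sigma2 <- 1e-12 * scale
      ll <- gaussian_loglik(n, sigma2)
      return(new_family_score(child, parents, ll - k / 2 * log(n), ll, k, n,
                              degenerate = TRUE, flag = "zero_variance", coefs = coefs))
    }
    return(new_family_score(child, parents, Inf, Inf, k, n,
                            degenerate = TRUE, flag = "zero_variance", coefs = coefs))
  }
  ll <- gaussian_loglik(n, sigma2)
  new_family_score(child, parents, ll - k / 2 * log(n), ll, k, n,
                   degenerate = FALSE, flag = flag, coefs = coefs)
}

#' BIC score of a multinomial family
#'
#' Estimates each conditional probability table row by the posterior mean
#' under a symmetric Dirichlet(`alpha`) prior, `(count + alpha) /
#' (rowsum + alpha * L)`, evaluates the log-likelihood at those estimates
#' (unobserved parent configurations contribute 0), and penalizes
#' `k = (L - 1) * prod(parent levels)` free parameters.  With `alpha = 0`
#' this is the plain MLE score; empty rows then fall back to a uniform
#' table row by convention.
#'
#' @param data Data frame or [score_context()].
#' @param child Discrete child column name.
#' @param parents Character vector of discrete parent names.
#' @param alpha Dirichlet pseudo-count (default 1).
#' @return A `family_score`.
#' @export
score_multinomial_family <- function(data, child, parents = character(0), alpha = 1) {
  ctx <- score_context(data)
  parents <- sort(as.character(parents))
  tpb_assert(child %in% ctx$disc, "invalid_argument", "child must be a discrete column")
  if (!all(parents %in% ctx$disc))
    tpb_error("mixed_constraint",
              "a discrete child may only be scored with discrete parents")
  L <- ctx$levels[[child]]
  plev <- ctx$levels[parents]
  ncfg <- max(1L, prod(plev))
  y <- ctx$D[, match(child, ctx$disc)]
  cfg <- if (length(parents)) {
    config_index(plev, ctx$D[, match(parents, ctx$disc), drop = FALSE])
  } else rep.int(1L, ctx$n)
  counts <- matrix(tabulate(cfg + ncfg * (y - 1L), ncfg * L), ncfg, L)
  rs <- rowSums(counts)
  phat <- (counts + alpha) / (rs + alpha * L)
  if (alpha == 0) phat[rs == 0L, ] <- 1 / L # empty-row convention
  pos <- counts > 0
  ll <- sum(counts[pos] * log(phat[pos]))
  k <- as.integer((L - 1L) * ncfg)
  n <- ctx$n
  new_family_score(child, parents, ll - k / 2 * log(n), ll, k, n)
}

#' BIC score of a conditional-Gaussian family
#'
#' Continuous child with a mixed parent set: rows are partitioned by the
#' discrete-parent configuration and a single linear model with shared
#' slopes on the continuous parents but one intercept per observed
#' configuration is fit, with a pooled residual variance.  `k =
#' #continuous parents + #observed configurations + 1`.  Configurations
#' with fewer rows than continuous parents + 1 are merged into one pooled
#' intercept group and flagged.  With no discrete parents this reduces
#' exactly to [score_gaussian_family()].
#'
#' @inheritParams score_gaussian_family
#' @param parents Character vector mixing discrete and continuous names.
#' @return A `family_score`.
#' @export
score_cgaussian_family <- function(data, child, parents = character(0)) {
  ctx <- score_context(data)
  parents <- sort(as.character(parents))
  tpb_assert(child %in% ctx$cont, "invalid_argument", "child must be a continuous column")
  tpb_assert(all(parents %in% ctx$names), "invalid_argument", "unknown parent column")
  dpar <- parents[ctx$kind[parents] == "discrete"]
  cpar <- parents[ctx$kind[parents] == "continuous"]
  if (length(dpar) == 0L) return(score_gaussian_family(ctx, child, cpar))
  n <- ctx$n
  cfg <- config_index(ctx$levels[dpar], ctx$D[, match(dpar, ctx$disc), drop = FALSE])
  flag <- NULL
  sizes <- table(cfg)
  small <- as.integer(names(sizes)[sizes < length(cpar) + 1L])
  if (length(small)) {
    # under-populated configurations share one pooled intercept
    cfg[cfg %in% small] <- -1L
    flag <- "pooled_small_configs"
  }
  g <- match(cfg, sort(unique(cfg)))
  m <- max(g)
  Gmat <- matrix(0, n, m)
  Gmat[cbind(seq_len(n), g)] <- 1
  X <- cbind(Gmat, ctx$Xc[, match(cpar, ctx$cont), drop = FALSE])
  y <- ctx$Xc[, match(child, ctx$cont)]
  if (n <= ncol(X) + 1L)
    tpb_error("insufficient_data", "too few rows for a conditional-Gaussian family")
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) flag <- c(flag, "rank_deficient")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  k <- as.integer(length(cpar) + m + 1L)
  scale <- max(1, mean(y^2))
  if (sigma2 < 1e-12 * scale)
    return(new_family_score(child, parents, Inf, Inf, k, n,
                            degenerate = TRUE, flag = "zero_variance"))
  ll <- gaussian_loglik(n, sigma2)
  co <- fit$coefficients
  coefs <- stats::setNames(co[m + seq_along(cpar)], cpar)
  new_family_score(child, parents, ll - k / 2 * log(n), ll, k, n,
                   flag = flag, coefs = coefs)
}

#' Score any admissible family
#'
#' Dispatches on the child's kind and the parent kinds: discrete child to
#' the multinomial score (discrete parents only), continuous child with at
#' least one discrete parent to the conditional-Gaussian score, otherwise
#' the linear-Gaussian score.
#'
#' @inheritParams score_multinomial_family
#' @return A `family_score`.
#' @export
score_family <- function(data, child, parents = character(0), alpha = 1) {
  ctx <- score_context(data)
  if (ctx$kind[[child]] == "discrete")
    return(score_multinomial_family(ctx, child, parents, alpha))
  if (any(ctx$kind[parents] == "discrete"))
    return(score_cgaussian_family(ctx, child, parents))
  score_gaussian_family(ctx, child, parents)
}

# memoized score_family on the context's cache
cached_score <- function(ctx, child, parents, alpha = 1) {
  key <- paste0(child, "|", paste(sort(parents), collapse = ","))
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  fs <- score_family(ctx, child, parents, alpha)
  assign(key, fs, envir = ctx$cache)
  fs
}

#' Global BIC of a DAG
#'
#' By decomposability, exactly the sum over nodes of the family score of
#' (node, parents-in-dag).
#'
#' @param dag A [typed_dag()] whose nodes are the data columns.
#' @param data Data frame or [score_context()].
#' @param alpha Dirichlet pseudo-count for discrete families.
#' @return The summed BIC (a scalar).
#' @export
global_bic <- function(dag, data, alpha = 1) {
  ctx <- score_context(data)
  tpb_assert(setequal(dag$nodes, ctx$names), "invalid_argument",
             "dag nodes must match data columns")
  sum(vapply(dag$nodes,
             function(v) cached_score(ctx, v, parents_of(dag, v), alpha)$bic,
             0))
}
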