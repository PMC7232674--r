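# Structure-recovery evaluation: strict directed-edge metrics, paired
# significance testing between learners, and the seeded benchmark loop.

#' Compare a learned structure against the truth
#'
#' Strict directed convention: a learned edge is a true positive only if it
#' matches a true edge in both endpoints and direction; a reversed true
#' edge counts as a false positive (and the missed true edge as a false
#' negative).  The false positive rate divides by all ordered non-true
#' pairs, `p(p-1) - |E_true|`.
#'
#' @param truth,learned [typed_dag()] objects over the same node set.  The
#'   learned argument may also be any list with `nodes` and `edges`
#'   entries, so the directed edge set of a tool that can emit cycles is
#'   still comparable.
#' @param skeleton If `TRUE`, compare undirected adjacencies instead
#'   (secondary panel): a reversed edge then counts as a true positive and
#'   the FPR denominator is the number of unordered non-adjacent pairs.
#' @return Object of class `structure_metrics`: `tp`, `fp`, `fn`, `tpr`,
#'   `precision` (0 with `precision_undefined = TRUE` when no edge was
#'   learned), `fpr`.
#' @export
#' @examples
#' v <- data.frame(name = c("A", "B", "C"), kind = "continuous", levels = NA)
#' t <- typed_dag(v, data.frame(parent = c("A", "B", "A"), child = c("B", "C", "C")))
#' l <- typed_dag(v, data.frame(parent = c("A", "B", "C"), child = c("B", "C", "A")))
#' compare_structures(t, l)
compare_structures <- function(truth, learned, skeleton = FALSE) {
  if (!setequal(truth$nodes, learned$nodes))
    tpb_error("invalid_comparison", "truth and learned graphs have different node sets")
  p <- length(truth$nodes)
  key <- function(e) {
    if (skeleton) unique(paste(pmin(e$parent, e$child),
                               pmax(e$parent, e$child), sep = "\r"))
    else paste(e$parent, e$child, sep = "\r")
  }
  te <- key(truth$edges)
  le <- key(learned$edges)
  tp <- length(intersect(te, le))
  fp <- length(le) - tp
  fn <- length(te) - tp
  denom_fpr <- if (skeleton) p * (p - 1) / 2 - length(te)
               else p * (p - 1) - length(te)
  undef <- tp + fp == 0L
  structure(list(
    tp = tp, fp = fp, fn = fn,
    tpr = if (tp + fn > 0) tp / (tp + fn) else 1,
    precision = if (undef) 0 else tp / (tp + fp),
    precision_undefined = undef,
    fpr = if (denom_fpr > 0) fp / denom_fpr else 0),
    class = "structure_metrics")
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d  TPR=%.4f  precision=%.4f%s  FPR=%.4f\n",
              x$tp, x$fp, x$fn, x$tpr, x$precision,
              if (x$precision_undefined) " (undefined->0)" else "", x$fpr))
  invisible(x)
}

#' Two-sided paired-sample t-test
#'
#' Classic paired t on the replicate-wise differences, with the two-sided
#' p-value from the t distribution with n-1 degrees of freedom.  When the
#' differences have zero variance the statistic is undefined and the
#' result carries `zero_variance = TRUE`, with p = 1 if all differences
#' are zero and p = 0 otherwise (the difference is then exactly constant).
#'
#' @param a,b Numeric vectors of equal length >= 2, paired by replicate.
#' @return List with `t`, `p`, `df`, `mean_diff`, `zero_variance`.
#' @export
paired_t_test <- function(a, b) {
  tpb_assert(length(a) == length(b) && length(a) >= 2,
             "invalid_argument", "need paired vectors of equal length >= 2")
  d <- a - b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s < 1e-14 * max(1, abs(m))) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p = if (m == 0) 1 else 0,
                df = n - 1L, mean_diff = m, zero_variance = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1L,
       mean_diff = m, zero_variance = FALSE)
}

#' Built-in learners for benchmarking
#'
#' @return Named list of functions `(data, search_config) -> bn_learn`:
#'   the two-phase learner and the hill-climbing baseline.
#' @export
default_learners <- function() {
  list(two_phase = function(data, config) learn(data, config),
       hill_climb = function(data, config) hill_climb_baseline(data, config))
}

#' Run a structure-recovery benchmark
#'
#' For every configuration and replicate: simulate an instance, let each
#' learner recover the structure, and evaluate it with
#' [compare_structures()].  A learner failure on one replicate is recorded
#' as missing, not fatal.  Aggregates report the per-setting median and
#' IQR of every metric, and a paired t-test matrix compares each pair of
#' learners per setting and metric (with a Holm-adjusted column).
#'
#' @param grid List of [sim_config()] settings (replicate seeds are derived
#'   internally).
#' @param learners Named list of learner functions; defaults to
#'   [default_learners()].
#' @param search A [search_config()] passed to every learner.
#' @param replicates Replicates per setting.
#' @param base_seed Base seed for replicate-seed derivation.
#' @return Object of class `benchmark_result` with data frames `results`
#'   (one row per setting x replicate x learner), `aggregates` and
#'   `ttests`.
#' @export
run_benchmark <- function(grid, learners = default_learners(),
                          search = search_config(), replicates = 1L,
                          base_seed = 1L) {
  tpb_assert(length(grid) > 0 && length(learners) > 0,
             "invalid_argument", "grid and learners must be nonempty")
  tpb_assert(!is.null(names(learners)) && all(nzchar(names(learners))),
             "invalid_argument", "learners must be named")
  rows <- list()
  ri <- 0L
  for (gi in seq_along(grid)) {
    cfg <- grid[[gi]]
    setting <- cfg$setting %||%
      sprintf("%s_%s_p%d_n%d", cfg$network_kind, cfg$topology, cfg$p, cfg$n)
    for (r in seq_len(replicates)) {
      cfg$seed <- derive_seed(base_seed, (gi - 1L) * replicates + r)
      inst <- simulate_instance(cfg)
      for (ln in names(learners)) {
        t0 <- proc.time()[["elapsed"]]
        fit <- tryCatch(learners[[ln]](inst$data, search), error = function(e) NULL)
        elapsed <- proc.time()[["elapsed"]] - t0
        ri <- ri + 1L
        if (is.null(fit)) {
          rows[[ri]] <- data.frame(setting = setting, replicate = r, learner = ln,
                                   tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                                   tpr = NA_real_, precision = NA_real_, fpr = NA_real_,
                                   elapsed = elapsed, stringsAsFactors = FALSE)
        } else {
          dag <- if (inherits(fit, "bn_learn")) fit$dag else fit
          m <- compare_structures(inst$truth$dag, dag)
          rows[[ri]] <- data.frame(setting = setting, replicate = r, learner = ln,
                                   tp = m$tp, fp = m$fp, fn = m$fn,
                                   tpr = m$tpr, precision = m$precision, fpr = m$fpr,
                                   elapsed = elapsed, stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)

  metrics <- c("tpr", "precision", "fpr")
  agg <- list()
  ai <- 0L
  for (s in unique(results$setting)) for (ln in names(learners)) {
    sub <- results[results$setting == s & results$learner == ln, ]
    for (mt in metrics) {
      ai <- ai + 1L
      x <- sub[[mt]]
      agg[[ai]] <- data.frame(setting = s, learner = ln, metric = mt,
                              median = stats::median(x, na.rm = TRUE),
                              iqr = stats::IQR(x, na.rm = TRUE),
                              n = sum(!is.na(x)), stringsAsFactors = FALSE)
    }
  }
  aggregates <- do.call(rbind, agg)

  tt <- list()
  ti <- 0L
  lns <- names(learners)
  if (length(lns) >= 2L && replicates >= 2L) {
    for (s in unique(results$setting)) for (mt in metrics) {
      for (i in seq_len(length(lns) - 1L)) for (j in (i + 1L):length(lns)) {
        a <- results[results$setting == s & results$learner == lns[i], mt]
        b <- results[results$setting == s & results$learner == lns[j], mt]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < 2L) next
        tr <- paired_t_test(a[ok], b[ok])
        ti <- ti + 1L
        tt[[ti]] <- data.frame(setting = s, metric = mt,
                               learner_a = lns[i], learner_b = lns[j],
                               t = tr$t, p = tr$p, df = tr$df,
                               zero_variance = tr$zero_variance,
                               stringsAsFactors = FALSE)
      }
    }
  }
  ttests <- if (ti > 0L) {
    out <- do.call(rbind, tt)
    out$p_holm <- stats::p.adjust(out$p, method = "holm")
    out
  } else {
    data.frame(setting = character(0), metric = character(0),
               learner_a = character(0), learner_b = character(0),
               t = numeric(0), p = numeric(0), df = integer(0),
               zero_variance = logical(0), p_holm = numeric(0))
  }
  structure(list(results = results, aggregates = aggregates, ttests = ttests),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d runs over %d settings\n",
              nrow(x$results), length(unique(x$results$setting))))
  print(x$aggregates)
  invisible(x)
}
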