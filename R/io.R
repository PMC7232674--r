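# File formats: delimited datasets with per-column type declarations,
# tab-separated weighted edge lists with a variables sidecar, dense
# adjacency matrices, and JSON run manifests for exact replay.

#' Read a delimited dataset with typed columns
#'
#' Reads a rectangular, headered, delimited text file and types every
#' column either from an explicit declaration or by inference: a column
#' whose values are integer-like with at most 6 distinct values becomes
#' discrete (a factor over the sorted observed values), anything else must
#' parse as numeric and becomes continuous.  Missing values are rejected.
#'
#' @param path File path.
#' @param types Optional declaration: a data frame with columns `name`,
#'   `kind` and optionally `levels` (comma-separated level labels), or the
#'   path to such a table in TSV form.  `NULL` (default) infers types and
#'   reports the inference with a message.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return Data frame with numeric and factor columns.
#' @export
read_dataset <- function(path, types = NULL, sep = ",") {
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) tpb_error("parse_error", conditionMessage(e)))
  tpb_assert(nrow(raw) >= 1 && ncol(raw) >= 1, "parse_error", "empty dataset")
  na_cells <- which(raw == "NA" | raw == "" | is.na(as.matrix(raw)), arr.ind = TRUE)
  if (nrow(na_cells))
    tpb_error("parse_error",
              sprintf("missing value at row %d, column '%s' (missing data unsupported)",
                      na_cells[1L, 1L], names(raw)[na_cells[1L, 2L]]))

  if (is.character(types)) {
    types <- utils::read.table(types, header = TRUE, sep = "\t",
                               colClasses = "character", stringsAsFactors = FALSE)
  }
  out <- raw
  inferred <- character(0)
  for (j in seq_along(raw)) {
    nm <- names(raw)[j]
    v <- raw[[j]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.null(types)) {
      row <- which(types$name == nm)
      tpb_assert(length(row) == 1L, "parse_error",
                 sprintf("column '%s' not covered exactly once by the type declaration", nm))
      kind <- types$kind[row]
      if (kind == "continuous") {
        if (anyNA(num))
          tpb_error("parse_error",
                    sprintf("non-numeric value at row %d, column '%s'",
                            which(is.na(num))[1L], nm))
        out[[j]] <- num
      } else {
        lev <- if ("levels" %in% names(types) && nzchar(types$levels[row] %||% "")) {
          strsplit(types$levels[row], ",", fixed = TRUE)[[1L]]
        } else sort(unique(v))
        if (!all(v %in% lev))
          tpb_error("parse_error",
                    sprintf("unseen level '%s' at row %d, column '%s'",
                            v[!v %in% lev][1L], which(!v %in% lev)[1L], nm))
        out[[j]] <- factor(v, levels = lev)
      }
    } else {
      if (anyNA(num))
        tpb_error("parse_error",
                  sprintf("non-numeric value at row %d, column '%s'",
                          which(is.na(num))[1L], nm))
      u <- unique(num)
      if (length(u) <= 6L && all(abs(num - round(num)) < 1e-8)) {
        out[[j]] <- factor(as.integer(round(num)), levels = sort(unique(as.integer(round(u)))))
        inferred <- c(inferred, sprintf("%s=discrete(%d levels)", nm, length(u)))
      } else {
        out[[j]] <- num
        inferred <- c(inferred, sprintf("%s=continuous", nm))
      }
    }
  }
  if (length(inferred))
    message("inferred column types: ", paste(inferred, collapse = ", "))
  out
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a typed DAG as a weighted edge list plus variables sidecar
#'
#' The edge list is tab-separated with header `parent  child  weight`
#' (weights default to 1.0); the sidecar lists `name  kind  levels`.
#' Weights are written at full double precision so the round-trip through
#' [read_network()] is exact.
#'
#' @param dag A [typed_dag()].
#' @param edges_path,vars_path Output file paths.
#' @param weights Optional data frame `parent`, `child`, `weight` or a
#'   numeric vector aligned with `dag$edges`.
#' @return Invisibly, the edge data frame written.
#' @export
write_network <- function(dag, edges_path, vars_path, weights = NULL) {
  ed <- dag$edges
  w <- rep(1, nrow(ed))
  if (!is.null(weights)) {
    if (is.data.frame(weights)) {
      key <- paste(ed$parent, ed$child, sep = "\r")
      wk <- paste(weights$parent, weights$child, sep = "\r")
      idx <- match(key, wk)
      w[!is.na(idx)] <- weights$weight[idx[!is.na(idx)]]
    } else {
      tpb_assert(length(weights) == nrow(ed), "invalid_argument",
                 "weights must align with dag edges")
      w <- as.numeric(weights)
    }
  }
  lines <- c("parent\tchild\tweight",
             if (nrow(ed)) paste(ed$parent, ed$child, fmt_num(w), sep = "\t"))
  writeLines(lines, edges_path)
  vl <- c("name\tkind\tlevels",
          paste(dag$nodes, dag$kind[dag$nodes],
                ifelse(is.na(dag$levels[dag$nodes]), "", dag$levels[dag$nodes]),
                sep = "\t"))
  writeLines(vl, vars_path)
  invisible(cbind(ed, weight = w))
}

#' Read a typed DAG written by [write_network()]
#'
#' @param edges_path,vars_path Paths written by [write_network()].
#' @return A [typed_dag()]; the edge weights are attached as attribute
#'   `"weights"` (data frame `parent`, `child`, `weight`).
#' @export
read_network <- function(edges_path, vars_path) {
  vars <- utils::read.table(vars_path, header = TRUE, sep = "\t",
                            colClasses = "character", stringsAsFactors = FALSE,
                            fill = FALSE)
  vars$levels <- suppressWarnings(as.integer(vars$levels))
  ed <- utils::read.table(edges_path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"),
                          stringsAsFactors = FALSE)
  if (nrow(ed) && !all(c(ed$parent, ed$child) %in% vars$name))
    tpb_error("parse_error", "edge list references a node missing from the variables file")
  dag <- typed_dag(vars, ed[c("parent", "child")])
  key <- paste(dag$edges$parent, dag$edges$child, sep = "\r")
  w <- ed$weight[match(key, paste(ed$parent, ed$child, sep = "\r"))]
  attr(dag, "weights") <- cbind(dag$edges, weight = if (nrow(dag$edges)) w else numeric(0))
  dag
}

#' Write a dense adjacency matrix with node-name headers
#'
#' Rows are parents, columns children; entries are edge weights (0 for no
#' edge).
#'
#' @inheritParams write_network
#' @param path Output file path.
#' @return Invisibly, the adjacency matrix.
#' @export
write_adjacency <- function(dag, path, weights = NULL) {
  nm <- sort(dag$nodes)
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  ed <- dag$edges
  w <- rep(1, nrow(ed))
  if (!is.null(weights) && is.data.frame(weights)) {
    idx <- match(paste(ed$parent, ed$child, sep = "\r"),
                 paste(weights$parent, weights$child, sep = "\r"))
    w[!is.na(idx)] <- weights$weight[idx[!is.na(idx)]]
  }
  if (nrow(ed)) A[cbind(ed$parent, ed$child)] <- w
  lines <- c(paste(c("node", nm), collapse = "\t"),
             vapply(nm, function(r)
               paste(c(r, fmt_num(A[r, ])), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(A)
}

#' Read an adjacency matrix written by [write_adjacency()] as an edge list
#'
#' @param path Adjacency file path.
#' @return Data frame `parent`, `child`, `weight` for all nonzero entries.
#' @export
read_adjacency <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1)
  A <- as.matrix(tab)
  idx <- which(A != 0, arr.ind = TRUE)
  out <- data.frame(parent = rownames(A)[idx[, 1L]],
                    child = colnames(A)[idx[, 2L]],
                    weight = A[idx], stringsAsFactors = FALSE)
  out[order(out$child, out$parent), , drop = FALSE]
}

#' Build a run manifest
#'
#' Records the package version, the full configuration, every seed and the
#' MD5 hashes of the run's files, so a run can be replayed exactly.
#'
#' @param config A configuration object (list-like); coerced to a plain
#'   list.
#' @param seeds Named list or vector of the seeds used.
#' @param files Character vector of file paths to hash.
#' @return List ready for [jsonlite::write_json()].
#' @export
run_manifest <- function(config, seeds, files = character(0)) {
  hashes <- if (length(files)) {
    h <- tools::md5sum(files)
    stats::setNames(as.vector(h), basename(files))
  } else NULL
  list(tool = "twophasebn",
       version = as.character(utils::packageVersion("twophasebn")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       config = unclass(config),
       seeds = as.list(seeds),
       input_hashes = hashes)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
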