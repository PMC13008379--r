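# Strength-type graph measures, group SC differences, subject-relabeling
# permutation tests, and Benjamini-Hochberg FDR control.

#' Graph strength
#'
#' Sum of connection weights across the network, each undirected edge
#' counted once. Absent edges contribute nothing; on an unthresholded
#' network negative correlations contribute their sign.
#'
#' @param net an `scn`.
#' @return numeric scalar.
#' @export
graph_strength <- function(net) {
  sum(net$weights[upper.tri(net$weights)], na.rm = TRUE)
}

#' Node strength (weighted degree) centrality
#'
#' Sum of the weights of edges incident to a node. With `node = NULL`,
#' returns the named strength vector for all nodes.
#'
#' @param net an `scn`.
#' @param node node label, or `NULL` for all nodes.
#' @return numeric scalar or named vector.
#' @export
node_strength <- function(net, node = NULL) {
  s <- rowSums(net$weights, na.rm = TRUE)
  names(s) <- net$labels
  if (is.null(node)) return(s)
  if (!node %in% net$labels) stop("unknown node: ", node)
  s[[node]]
}

#' Between-group edge-weight difference (SC_diff)
#'
#' Elementwise case-minus-control difference of two group networks over
#' identical node sets and edge masks.
#'
#' @param case_net,control_net `scn` objects with identical labels and
#'   masks.
#' @return object of class `sc_diff` with fields `labels`, `delta`
#'   (matrix, `NA` on absent edges) and `partition`.
#' @export
sc_diff <- function(case_net, control_net) {
  if (!identical(case_net$labels, control_net$labels))
    stop("node sets differ between networks")
  if (!identical(is.na(case_net$weights), is.na(control_net$weights)))
    stop("edge masks differ between networks")
  structure(list(labels = case_net$labels,
                 delta = case_net$weights - control_net$weights,
                 partition = case_net$partition),
            class = "sc_diff")
}

# ---- statistic factories for permutation tests ------------------------

# lean correlation-network statistic machinery: each statistic maps the
# two groups' residual matrices (subjects x regions) to a named vector

.cor_masked <- function(Y, setA = NULL, labels = colnames(Y)) {
  W <- stats::cor(Y)
  diag(W) <- NA
  if (!is.null(setA)) {
    ia <- labels %in% setA
    W[ia, ia] <- NA
    W[!ia, !ia] <- NA
  }
  W
}

#' Statistic factories for [permutation_test()]
#'
#' Each factory returns a function mapping the case and control residual
#' matrices to a named vector of group-difference statistics, rebuilding
#' the correlation networks from scratch:
#' \describe{
#'   \item{`stat_graph_strength`}{graph-strength difference, one value per
#'     threshold (`NULL` entries meaning unthresholded).}
#'   \item{`stat_node_strength`}{node-strength difference for every node
#'     (50 thalamic nuclei in the default networks).}
#'   \item{`stat_edge_weights`}{edge-weight difference (SC_diff) for every
#'     present edge, named `"i|j"`.}
#' }
#'
#' @param nodes region columns forming the network.
#' @param setA,setB optional bipartite partition (labels); within-set
#'   edges are removed before measuring.
#' @param thresholds list of thresholds (`list(NULL)` = unthresholded
#'   only) for the graph-strength statistic.
#' @return function `(case_matrix, control_matrix) -> named numeric`.
#' @name stat_factories
NULL

.stat_prep <- function(Y, nodes, setA) {
  W <- .cor_masked(Y[, nodes, drop = FALSE], setA, nodes)
  W
}

#' @rdname stat_factories
#' @export
stat_graph_strength <- function(nodes, setA = NULL, setB = NULL,
                                thresholds = list(NULL)) {
  force(nodes); force(setA); force(thresholds)
  function(case_mat, ctrl_mat) {
    Wc <- .stat_prep(case_mat, nodes, setA)
    Wx <- .stat_prep(ctrl_mat, nodes, setA)
    ut <- upper.tri(Wc)
    vapply(thresholds, function(t) {
      if (is.null(t)) {
        sum(Wc[ut], na.rm = TRUE) - sum(Wx[ut], na.rm = TRUE)
      } else {
        sum(Wc[ut & !is.na(Wc) & Wc > t]) - sum(Wx[ut & !is.na(Wx) & Wx > t])
      }
    }, numeric(1)) |>
      stats::setNames(vapply(thresholds, function(t)
        if (is.null(t)) "unthresholded" else sprintf("t=%.3f", t),
        character(1)))
  }
}

#' @rdname stat_factories
#' @export
stat_node_strength <- function(nodes, setA = NULL, setB = NULL) {
  force(nodes); force(setA)
  function(case_mat, ctrl_mat) {
    Wc <- .stat_prep(case_mat, nodes, setA)
    Wx <- .stat_prep(ctrl_mat, nodes, setA)
    s <- rowSums(Wc, na.rm = TRUE) - rowSums(Wx, na.rm = TRUE)
    stats::setNames(s, nodes)
  }
}

#' @rdname stat_factories
#' @export
stat_edge_weights <- function(nodes, setA = NULL, setB = NULL) {
  force(nodes); force(setA)
  function(case_mat, ctrl_mat) {
    Wc <- .stat_prep(case_mat, nodes, setA)
    Wx <- .stat_prep(ctrl_mat, nodes, setA)
    idx <- which(upper.tri(Wc) & is.finite(Wc), arr.ind = TRUE)
    stats::setNames(Wc[idx] - Wx[idx],
                    paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "|"))
  }
}

#' Subject-relabeling permutation test of a network statistic
#'
#' Shuffles diagnostic labels across subjects while keeping group sizes
#' constant, rebuilds the group networks from the residuals under each
#' relabeling, and compares the observed group difference with the null
#' sample. Two-sided p per component: `p = (b + 1) / (m + 1)` with `b` the
#' number of permutations whose absolute null difference equals or
#' exceeds the absolute observed difference. When the statistic returns a
#' vector (a comparison family: thresholds, nodes, or edges), the same
#' permutation labelings are reused across all components and the family
#' is BH-corrected jointly.
#'
#' @param pooled ResidualTable (or data.frame/matrix) holding all
#'   subjects' region residuals.
#' @param labels group label per subject (exactly two levels).
#' @param statistic function `(case_matrix, control_matrix) -> named
#'   numeric`, e.g. from [stat_graph_strength()].
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param case_level label treated as the case group (default
#'   `"case"` if present, else the first level).
#' @param family comparison-family tag carried into the result.
#' @return object of class `perm_test`: `observed`, `null` (matrix
#'   `n_perm x k`), `p`, `p_fdr`, `n_perm`, `seed`, `family`.
#' @export
permutation_test <- function(pooled, labels, statistic, n_perm = 5000,
                             seed = 1L, case_level = NULL,
                             family = "unnamed") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must have exactly two groups")
  if (is.null(case_level))
    case_level <- if ("case" %in% lv) "case" else lv[1]
  if (!case_level %in% lv) stop("case_level not found in labels")
  M <- if (is.matrix(pooled)) pooled else {
    df <- as.data.frame(pooled)
    as.matrix(df[, vapply(df, is.numeric, logical(1)), drop = FALSE])
  }
  if (nrow(M) != length(labels))
    stop("labels length does not match subject count")
  is_case <- labels == case_level
  if (!any(is_case) || all(is_case)) stop("both groups must be nonempty")
  obs <- statistic(M[is_case, , drop = FALSE], M[!is_case, , drop = FALSE])
  k <- length(obs)
  null <- matrix(NA_real_, n_perm, k)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    sh <- sample(is_case)
    null[b, ] <- statistic(M[sh, , drop = FALSE], M[!sh, , drop = FALSE])
  }
  colnames(null) <- names(obs)
  p <- (colSums(sweep(abs(null), 2, abs(obs), `>=`)) + 1) / (n_perm + 1)
  structure(list(observed = obs, null = null, p = p,
                 p_fdr = bh_fdr(p, family = family),
                 n_perm = n_perm, seed = seed, family = family,
                 case_level = case_level),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> family=%s, %d comparison(s), %d permutations\n",
              x$family, length(x$observed), x$n_perm))
  print(utils::head(data.frame(observed = x$observed, p = x$p,
                               p_fdr = x$p_fdr), 10))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Validates the inputs and applies the standard BH step-up adjustment
#' (monotone, capped at 1). The rejection set at level `q` is
#' `{p_fdr < q}`.
#'
#' @param p_values p-values in `(0, 1]`.
#' @param family family tag (for bookkeeping; adjustment is within the
#'   supplied vector).
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p_values, family = "unnamed") {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Tidy export of permutation-test results
#'
#' @param x a `perm_test`.
#' @param file optional TSV path.
#' @return data.frame `(family, comparison, observed, p, p_fdr)`.
#' @export
perm_test_table <- function(x, file = NULL) {
  df <- data.frame(family = x$family,
                   comparison = names(x$observed),
                   observed = unname(x$observed),
                   p = unname(x$p), p_fdr = unname(x$p_fdr))
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  df
}
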