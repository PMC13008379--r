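# Group-level structural covariance networks: correlation matrices over
# residualized regional volumes, bipartite masking, threshold sweeps
# bounded by minimum wiring cost.

#' Covariance network object
#'
#' A labeled symmetric edge-weight matrix of pairwise Pearson correlations
#' for one group. Absent edges (the diagonal, thresholded-out edges, and
#' within-set edges of bipartite networks) are `NA`.
#'
#' @param weights square symmetric numeric matrix with dimnames; `NA`
#'   marks absent edges; finite entries must lie in `[-1, 1]`.
#' @param group group tag (e.g. `"case"`, `"control"`).
#' @param n_subjects number of subjects the correlations were computed on.
#' @param partition `NULL`, or `list(A =, B =)` node label sets for
#'   bipartite networks.
#' @return object of class `scn`.
#' @export
new_scn <- function(weights, group = NA_character_, n_subjects = NA_integer_,
                    partition = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights),
            !is.null(colnames(weights)))
  d <- weights; diag(d) <- NA
  fin <- which(is.finite(d))
  if (length(fin) && (max(abs(d[fin] - t(d)[fin])) > 1e-12))
    stop("weight matrix is not symmetric")
  if (length(fin) && max(abs(d[fin])) > 1 + 1e-12)
    stop("edge weights must lie in [-1, 1]")
  diag(weights) <- NA
  structure(list(weights = weights, labels = colnames(weights),
                 group = group, n_subjects = n_subjects,
                 partition = partition),
            class = "scn")
}

#' @export
print.scn <- function(x, ...) {
  cat(sprintf("<scn> %d nodes, %d edges, group=%s, n=%s%s\n",
              length(x$labels), n_edges(x), x$group, x$n_subjects,
              if (is.null(x$partition)) "" else
                sprintf(", bipartite %dx%d", length(x$partition$A),
                        length(x$partition$B))))
  invisible(x)
}

#' Number of present (non-absent) edges
#' @param net an `scn`.
#' @return integer edge count (each undirected edge counted once).
#' @export
n_edges <- function(net) {
  sum(is.finite(net$weights[upper.tri(net$weights)]))
}

#' Build a group structural covariance network
#'
#' Edge weights are Pearson correlations between region residuals across
#' the subjects of one group.
#'
#' @param residuals ResidualTable (or any data.frame/matrix of region
#'   columns); if a `group` column is present, rows are subset by `group`.
#' @param nodes region columns to use as network nodes.
#' @param group group tag used for subsetting/labeling.
#' @return an [new_scn()] object.
#' @export
build_scn <- function(residuals, nodes, group = NA_character_) {
  tab <- residuals
  if (!is.na(group) && "group" %in% names(tab))
    tab <- tab[tab$group == group, , drop = FALSE]
  Y <- .region_cols(as.data.frame(tab), nodes)
  if (nrow(Y) < 4) stop("need at least 4 subjects to build an SCN")
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(nodes[sds == 0], collapse = ", "))
  W <- stats::cor(Y)
  new_scn(W, group = group, n_subjects = nrow(Y))
}

#' Restrict a network to its bipartite (A-B) edges
#'
#' Removes all within-set edges, leaving only connections between the two
#' node sets (e.g. thalamic nuclei vs cortical regions), so that exactly
#' `|A| * |B|` edges remain.
#'
#' @param net an `scn` whose nodes are covered by `setA` and `setB`.
#' @param setA,setB disjoint node label sets.
#' @return bipartite `scn`.
#' @export
extract_bipartite <- function(net, setA, setB) {
  if (length(intersect(setA, setB)))
    stop("setA and setB must be disjoint")
  if (!setequal(c(setA, setB), net$labels))
    stop("setA and setB must cover the network's nodes")
  W <- net$weights
  ia <- net$labels %in% setA
  W[ia, ia] <- NA
  W[!ia, !ia] <- NA
  new_scn(W, group = net$group, n_subjects = net$n_subjects,
          partition = list(A = setA, B = setB))
}

#' Threshold a weighted network
#'
#' Retains edges with weight strictly greater than `t` at their original
#' (signed) weight; `t = NULL` is the "unthresholded" sentinel and returns
#' the network unchanged, negative correlations included.
#'
#' @param net an `scn`.
#' @param t non-negative threshold, or `NULL` for unthresholded.
#' @return thresholded `scn`.
#' @export
threshold_graph <- function(net, t) {
  if (is.null(t)) return(net)
  if (t < 0) stop("threshold must be >= 0 (use NULL for unthresholded)")
  W <- net$weights
  W[!is.na(W) & W <= t] <- NA
  out <- net
  out$weights <- W
  out
}

.is_connected_at <- function(net, t) {
  A <- !is.na(net$weights) & net$weights > t
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::is_connected(g)
}

#' Minimum-wiring-cost threshold of a network
#'
#' Sweeps thresholds upward from 0 in fixed steps and returns the largest
#' grid threshold at which the binarized graph still has no disconnected
#' nodes (every node reachable from every other; bipartite networks are
#' assessed over both node sets jointly). This is the threshold of lowest
#' edge density with a fully connected graph, and it bounds the threshold
#' sweep used for group comparison.
#'
#' @param net an `scn`, connected at threshold 0.
#' @param step grid step (default 0.025).
#' @return largest connected grid threshold, with attribute
#'   `edge_density` (edges present / possible edges at that threshold).
#' @export
min_wiring_cost_threshold <- function(net, step = 0.025) {
  if (!.is_connected_at(net, 0))
    stop("network is disconnected at threshold 0")
  t <- 0
  repeat {
    t_next <- t + step
    if (t_next >= 1 || !.is_connected_at(net, t_next)) break
    t <- t_next
  }
  thr <- threshold_graph(net, t)
  possible <- if (is.null(net$partition))
    length(net$labels) * (length(net$labels) - 1) / 2
  else length(net$partition$A) * length(net$partition$B)
  structure(t, edge_density = n_edges(thr) / possible)
}

#' Threshold grid shared by two groups
#'
#' Ascending grid from 0 in steps of `step`, capped at the smaller of the
#' two groups' minimum-wiring-cost thresholds (the sweep stops when the
#' threshold reaches the minimum wiring cost for one of the groups).
#'
#' @param net_a,net_b the two group networks.
#' @param step grid step.
#' @return numeric vector of thresholds.
#' @export
threshold_sweep <- function(net_a, net_b, step = 0.025) {
  cap <- min(as.numeric(min_wiring_cost_threshold(net_a, step)),
             as.numeric(min_wiring_cost_threshold(net_b, step)))
  seq(0, cap, by = step)
}

#' Write a network as an adjacency CSV / long edge list
#'
#' @param net an `scn`.
#' @param file output path; `write_scn_edges` writes a long-format
#'   `(node_i, node_j, weight)` TSV of present edges.
#' @return the path, invisibly.
#' @export
write_scn <- function(net, file) {
  utils::write.csv(as.data.frame(net$weights), file, row.names = TRUE)
  invisible(file)
}

#' @rdname write_scn
#' @export
write_scn_edges <- function(net, file) {
  W <- net$weights
  idx <- which(upper.tri(W) & is.finite(W), arr.ind = TRUE)
  df <- data.frame(node_i = net$labels[idx[, 1]],
                   node_j = net$labels[idx[, 2]],
                   weight = W[idx])
  utils::write.table(df, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
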