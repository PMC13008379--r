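# Hierarchical clustering of thalamic nuclei by their covariance-
# difference (SC_diff) profiles: correlation-distance profiles, average
# linkage, Kelley-Gardner-Sutcliffe cluster-count selection, and
# dendrogram comparison via cophenetic correlation.

#' Profile distance between network nodes
#'
#' Each leaf's profile is its row of the SC_diff matrix restricted to
#' `columns` (all partner nodes for an intrathalamic network; the
#' cortical side for a bipartite network), self-entries excluded. The
#' default distance is correlation distance `1 - r` (range `[0, 2]`),
#' capturing the shape of the difference pattern; Euclidean distance is
#' available by option.
#'
#' @param scdiff an `sc_diff` (or plain matrix with dimnames).
#' @param leaves node subset to cluster (>= 3).
#' @param columns profile columns; defaults to the bipartite B side if
#'   present, else all nodes.
#' @param method `"correlation"` or `"euclidean"`.
#' @return symmetric distance matrix over `leaves`.
#' @export
profile_distance <- function(scdiff, leaves = NULL, columns = NULL,
                             method = c("correlation", "euclidean")) {
  method <- match.arg(method)
  D <- if (inherits(scdiff, "sc_diff")) scdiff$delta else scdiff
  part <- if (inherits(scdiff, "sc_diff")) scdiff$partition else NULL
  if (is.null(leaves))
    leaves <- if (is.null(part)) rownames(D) else part$A
  if (is.null(columns))
    columns <- if (is.null(part)) colnames(D) else part$B
  if (length(leaves) < 3) stop("need at least 3 leaves")
  P <- D[leaves, columns, drop = FALSE]
  sds <- apply(P, 1, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad))
    stop("constant profile for leaf/leaves: ",
         paste(leaves[bad], collapse = ", "))
  if (method == "correlation") {
    # self-entries are NA in unipartite SC_diff rows; pairwise-complete
    # correlation drops each pair's self columns
    d <- 1 - stats::cor(t(P), use = "pairwise.complete.obs")
  } else {
    d <- as.matrix(stats::dist(P))
  }
  diag(d) <- 0
  d[d < 0] <- 0
  dimnames(d) <- list(leaves, leaves)
  d
}

#' Average-linkage agglomerative clustering
#'
#' Unweighted average linkage (UPGMA): the closest pair of clusters is
#' merged and inter-cluster distance is the mean over all cross pairs.
#'
#' @param dist symmetric distance matrix (or `dist`).
#' @return an [stats::hclust] dendrogram (merge list + non-decreasing
#'   heights).
#' @export
average_linkage <- function(dist) {
  if (is.matrix(dist)) {
    if (max(abs(dist - t(dist))) > 1e-10)
      stop("distance matrix is not symmetric")
    dist <- stats::as.dist(dist)
  }
  stats::hclust(dist, method = "average")
}

#' Select the number of clusters by the KGS penalty
#'
#' For each candidate cut into `k` clusters (`k` in `2 .. L-1`), the
#' spread is the mean, over clusters with at least two members, of the
#' mean pairwise distance within the cluster. Spreads are linearly
#' rescaled across candidates onto `[1, L - 1]`, and the penalty is
#' `alpha * rescaled_spread(k) + k`. The selected `k` minimizes the
#' penalty (smallest `k` on ties).
#'
#' @param dend an `hclust` dendrogram.
#' @param dist the distance matrix the tree was built from.
#' @param alpha penalty weight (default 1).
#' @return list of class `kgs_selection`: `alpha`, `k` (selected),
#'   `candidates`, `spread`, `penalty`, `membership` (at selected `k`).
#' @export
kgs_optimal_k <- function(dend, dist, alpha = 1) {
  if (!inherits(dend, "hclust")) stop("dend must be an hclust tree")
  D <- if (is.matrix(dist)) dist else as.matrix(dist)
  L <- length(dend$labels)
  if (L < 4) stop("need at least 4 leaves")
  D <- D[dend$labels, dend$labels]
  ks <- 2:(L - 1)
  spread <- vapply(ks, function(k) {
    mem <- stats::cutree(dend, k = k)
    per <- vapply(split(names(mem), mem), function(lv) {
      if (length(lv) < 2) return(NA_real_)
      sub <- D[lv, lv]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    mean(per, na.rm = TRUE)
  }, numeric(1))
  rng <- range(spread)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("degenerate spread rescaling; falling back to k = 2")
    sel <- 2L
    penalty <- rep(NA_real_, length(ks))
  } else {
    resc <- (spread - rng[1]) / diff(rng) * (L - 2) + 1
    penalty <- alpha * resc + ks
    sel <- ks[which.min(penalty)]
  }
  structure(list(alpha = alpha, k = sel, candidates = ks,
                 spread = spread, penalty = penalty,
                 membership = stats::cutree(dend, k = sel)),
            class = "kgs_selection")
}

.cophenetic_matrix <- function(dend) {
  M <- as.matrix(stats::cophenetic(dend))
  M[dend$labels, dend$labels]
}

#' Cophenetic correlation between two dendrograms
#'
#' Correlation between the upper-triangle entries of the two trees'
#' cophenetic distance matrices (the height at which each pair of leaves
#' first joins), a standard measure of clustering similarity.
#'
#' @param dend_a,dend_b `hclust` trees over identical leaf sets. Either
#'   may instead be a distance matrix/`dist` (yielding the tree-vs-data
#'   cophenetic correlation used to vet the linkage choice).
#' @return Pearson correlation.
#' @export
cophenetic_correlation <- function(dend_a, dend_b) {
  as_mat <- function(x, labels) {
    if (inherits(x, "hclust")) return(.cophenetic_matrix(x))
    M <- if (is.matrix(x)) x else as.matrix(x)
    M[labels, labels]
  }
  labels <- if (inherits(dend_a, "hclust")) dend_a$labels
            else dend_b$labels
  A <- as_mat(dend_a, labels)
  B <- as_mat(dend_b, labels)
  if (!setequal(rownames(A), rownames(B)))
    stop("leaf sets differ between dendrograms")
  B <- B[rownames(A), rownames(A)]
  stats::cor(A[upper.tri(A)], B[upper.tri(B)])
}

.lowest_partners <- function(dend) {
  L <- length(dend$labels)
  members <- vector("list", nrow(dend$merge))
  leaves_of <- function(x) {
    if (x < 0) dend$labels[-x] else members[[x]]
  }
  partners <- stats::setNames(vector("list", L), dend$labels)
  for (m in seq_len(nrow(dend$merge))) {
    a <- leaves_of(dend$merge[m, 1])
    b <- leaves_of(dend$merge[m, 2])
    members[[m]] <- c(a, b)
    for (lf in a) if (is.null(partners[[lf]])) partners[[lf]] <- sort(b)
    for (lf in b) if (is.null(partners[[lf]])) partners[[lf]] <- sort(a)
  }
  partners
}

#' Machine-readable cluster pairing of two dendrograms
#'
#' For each leaf, records the set of leaves it first merges with
#' (its lowest-level partners) in each tree, whether the two trees agree
#' on that set (the colored connections a tanglegram would draw), and
#' the cluster memberships at the selected cut of each tree.
#'
#' @param dend_a,dend_b `hclust` trees over identical leaf sets.
#' @param k_a,k_b cluster counts for the membership columns (e.g. from
#'   [kgs_optimal_k()]); `NULL` omits them.
#' @return data.frame: `leaf`, `partners_a`, `partners_b`, `agree`,
#'   and optional `cluster_a`, `cluster_b`.
#' @export
cluster_pairing_export <- function(dend_a, dend_b, k_a = NULL,
                                   k_b = NULL) {
  if (!setequal(dend_a$labels, dend_b$labels))
    stop("leaf sets differ between dendrograms")
  pa <- .lowest_partners(dend_a)
  pb <- .lowest_partners(dend_b)
  leaves <- dend_a$labels
  out <- data.frame(
    leaf = leaves,
    partners_a = vapply(pa[leaves], paste, "", collapse = ","),
    partners_b = vapply(pb[leaves], paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  out$agree <- mapply(identical, pa[leaves], pb[leaves])
  if (!is.null(k_a))
    out$cluster_a <- stats::cutree(dend_a, k = k_a)[leaves]
  if (!is.null(k_b))
    out$cluster_b <- stats::cutree(dend_b, k = k_b)[leaves]
  out
}

#' Serialize a dendrogram
#'
#' @param dend an `hclust`.
#' @param file output path; `dend_to_newick` writes Newick,
#'   `dend_to_json` a JSON merge list with heights.
#' @return the path, invisibly (`dend_to_newick` returns the Newick
#'   string when `file` is `NULL`).
#' @export
dend_to_newick <- function(dend, file = NULL) {
  phy <- ape::as.phylo(dend)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(file)
}

#' @rdname dend_to_newick
#' @export
dend_to_json <- function(dend, file) {
  jsonlite::write_json(
    list(labels = dend$labels,
         merge = apply(dend$merge, 1, as.list),
         height = dend$height),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
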