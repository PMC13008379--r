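# Shared fixture builders; all randomness is locally seeded.

# small scn from an explicit weight matrix
toy_net <- function(W, labels = NULL, group = "case", n = 10L,
                    partition = NULL) {
  if (is.null(labels)) labels <- paste0("R", seq_len(ncol(W)))
  dimnames(W) <- list(labels, labels)
  new_scn(W, group = group, n_subjects = n, partition = partition)
}

# triangle graph with weights w12, w13, w23
triangle_net <- function(w12 = 0.1, w13 = 0.2, w23 = 0.3) {
  W <- matrix(NA_real_, 3, 3)
  W[1, 2] <- W[2, 1] <- w12
  W[1, 3] <- W[3, 1] <- w13
  W[2, 3] <- W[3, 2] <- w23
  toy_net(W)
}

# deterministic toy residual table: n subjects x regions, fixed values
toy_residuals <- function(n = 6, p = 4, seed = 42) {
  set.seed(seed)
  M <- matrix(round(rnorm(n * p), 3), n, p,
              dimnames = list(NULL, paste0("R", seq_len(p))))
  as.data.frame(M)
}

# independent elementwise Pearson correlation (brute-force oracle)
cor_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

cor_matrix_oracle <- function(M) {
  p <- ncol(M)
  W <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p))
    W[i, j] <- cor_oracle(M[, i], M[, j])
  dimnames(W) <- list(colnames(M), colnames(M))
  W
}

# independent BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent naive UPGMA trace: returns merge heights in order
upgma_heights_oracle <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- mean(D[clusters[[a]], clusters[[b]]])
      if (d < bd - 1e-15) { bd <- d; best <- c(a, b) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# synthetic leaf-profile matrix with g well-separated groups
grouped_profiles <- function(n_leaves, n_groups, n_cols = 40,
                             noise = 0.05, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_groups * n_cols, sd = 5), n_groups)
  grp <- rep(seq_len(n_groups), length.out = n_leaves)
  P <- centers[grp, ] + matrix(rnorm(n_leaves * n_cols, sd = noise),
                               n_leaves)
  dimnames(P) <- list(paste0("leaf", seq_len(n_leaves)),
                      paste0("c", seq_len(n_cols)))
  list(profiles = P, groups = grp)
}
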