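# Profile distances, average linkage, KGS selection, cophenetic
# comparison, cluster pairing.

test_that("profile distance is correlation distance on SC_diff rows", {
  P <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
             c = -c(1, 2, 3, 4), d = c(4, 1, 3, 2))
  colnames(P) <- paste0("x", 1:4)
  d <- profile_distance(P, leaves = rownames(P), columns = colnames(P))
  expect_equal(d["a", "b"], 0, tolerance = 1e-12)
  expect_equal(d["a", "c"], 2, tolerance = 1e-12)
  # brute-force oracle for every pair
  for (i in 1:4) for (j in 1:4)
    expect_equal(d[i, j],
                 max(0, 1 - cor_oracle(P[i, ], P[j, ])),
                 tolerance = 1e-12)
  expect_error(profile_distance(rbind(P, e = rep(1, 4)),
                                leaves = c(rownames(P), "e"),
                                columns = colnames(P)), "e")
})

test_that("unipartite profiles exclude self-entries via the NA mask", {
  set.seed(91)
  tab <- toy_residuals(30, 5, seed = 91)
  a <- build_scn(tab, paste0("R", 1:5))
  b <- build_scn(toy_residuals(30, 5, seed = 92), paste0("R", 1:5))
  d <- profile_distance(sc_diff(a, b))
  D <- sc_diff(a, b)$delta
  common <- setdiff(colnames(D), c("R1", "R2"))
  expect_equal(d["R1", "R2"],
               1 - cor_oracle(D["R1", common], D["R2", common]),
               tolerance = 1e-12)
})

test_that("average linkage reproduces forced merges and a manual trace", {
  D <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- average_linkage(D)
  expect_equal(hc$height, c(0.1, 1.0))
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("a", "b"))

  set.seed(92)
  M <- matrix(rnorm(5 * 6), 5)
  D5 <- as.matrix(dist(M))
  dimnames(D5) <- list(paste0("L", 1:5), paste0("L", 1:5))
  hc5 <- average_linkage(D5)
  expect_equal(hc5$height, upgma_heights_oracle(D5), tolerance = 1e-12)

  bad <- D; bad[1, 2] <- 0.5
  expect_error(average_linkage(bad), "symmetric")
})

test_that("merge heights are invariant to leaf order", {
  set.seed(93)
  D <- as.matrix(dist(matrix(rnorm(8 * 3), 8)))
  dimnames(D) <- list(paste0("L", 1:8), paste0("L", 1:8))
  perm <- sample(8)
  h1 <- sort(average_linkage(D)$height)
  h2 <- sort(average_linkage(D[perm, perm])$height)
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("KGS selection minimizes the penalty and recovers separated clouds", {
  set.seed(94)
  pts <- rbind(matrix(rnorm(8, 0, 0.1), 4),
               matrix(rnorm(8, 10, 0.1), 4),
               matrix(rnorm(8, 20, 0.1), 4))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("p", 1:12), paste0("p", 1:12))
  hc <- average_linkage(D)
  sel <- kgs_optimal_k(hc, D, alpha = 1)
  expect_equal(sel$k, 3)

  # exhaustive penalty oracle
  L <- 12
  ks <- 2:(L - 1)
  spread <- sapply(ks, function(k) {
    mem <- cutree(hc, k)
    mean(sapply(split(names(mem), mem), function(lv) {
      if (length(lv) < 2) return(NA_real_)
      sub <- D[lv, lv]; mean(sub[upper.tri(sub)])
    }), na.rm = TRUE)
  })
  resc <- (spread - min(spread)) / diff(range(spread)) * (L - 2) + 1
  expect_equal(sel$penalty, resc + ks, tolerance = 1e-12)
  expect_equal(sel$k, ks[which.min(resc + ks)])

  # alpha = 0 forces the smallest candidate
  expect_equal(kgs_optimal_k(hc, D, alpha = 0)$k, 2)

  # degenerate spreads fall back to k = 2 with a warning
  Deq <- matrix(1, 5, 5); diag(Deq) <- 0
  dimnames(Deq) <- list(paste0("q", 1:5), paste0("q", 1:5))
  expect_warning(res <- kgs_optimal_k(average_linkage(Deq), Deq),
                 "degenerate")
  expect_equal(res$k, 2)
})

test_that("cophenetic correlation compares trees as expected", {
  set.seed(95)
  D <- as.matrix(dist(matrix(rnorm(12 * 4), 12)))
  dimnames(D) <- list(paste0("L", 1:12), paste0("L", 1:12))
  hc <- average_linkage(D)
  expect_equal(cophenetic_correlation(hc, hc), 1)
  # matches the reference cophenetic computation against the data
  expect_equal(cophenetic_correlation(hc, D),
               cor(cophenetic(hc), as.dist(D)), tolerance = 1e-12)

  # hand-read cophenetic matrix of a forced 4-leaf toy
  D4 <- matrix(c(0, 0.1, 1, 1, 0.1, 0, 1, 1, 1, 1, 0, 0.2, 1, 1, 0.2, 0),
               4, 4, dimnames = list(letters[1:4], letters[1:4]))
  hc4 <- average_linkage(D4)
  M <- as.matrix(cophenetic(hc4))[letters[1:4], letters[1:4]]
  expect_equal(M["a", "b"], 0.1)
  expect_equal(M["c", "d"], 0.2)
  expect_equal(M["a", "c"], 1.0)

  # symmetry and relabeling invariance
  hc2 <- average_linkage(D4[c(2, 1, 4, 3), c(2, 1, 4, 3)])
  expect_equal(cophenetic_correlation(hc4, hc2), 1, tolerance = 1e-12)
  expect_equal(cophenetic_correlation(hc4, hc2),
               cophenetic_correlation(hc2, hc4))

  D5 <- D4; dimnames(D5) <- list(letters[5:8], letters[5:8])
  expect_error(cophenetic_correlation(hc4, average_linkage(D5)),
               "leaf sets")
})

test_that("unrelated random trees have low cophenetic correlation", {
  set.seed(96)
  rs <- replicate(100, {
    d1 <- as.matrix(dist(matrix(rnorm(20 * 5), 20)))
    d2 <- as.matrix(dist(matrix(rnorm(20 * 5), 20)))
    labs <- paste0("L", 1:20)
    dimnames(d1) <- dimnames(d2) <- list(labs, labs)
    cophenetic_correlation(average_linkage(d1), average_linkage(d2))
  })
  expect_lt(mean(abs(rs)), 0.3)
})

test_that("cluster pairing export records lowest-level partner agreement", {
  D <- matrix(1, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.1; D[3, 4] <- D[4, 3] <- 0.2
  dimnames(D) <- list(letters[1:4], letters[1:4])
  hc <- average_linkage(D)
  same <- cluster_pairing_export(hc, hc, k_a = 2, k_b = 2)
  expect_true(all(same$agree))
  expect_equal(same$cluster_a, same$cluster_b)

  # swap the pairings: (a,c), (b,d)
  D2 <- matrix(1, 4, 4); diag(D2) <- 0
  D2[1, 3] <- D2[3, 1] <- 0.1; D2[2, 4] <- D2[4, 2] <- 0.2
  dimnames(D2) <- list(letters[1:4], letters[1:4])
  diff <- cluster_pairing_export(hc, average_linkage(D2))
  expect_false(any(diff$agree))

  # half-shared structure: pairs (a,b) kept, (c,d) vs (c,e)/(d,f) broken
  D3 <- matrix(1, 6, 6); diag(D3) <- 0
  D3[1, 2] <- D3[2, 1] <- 0.1
  D3[3, 4] <- D3[4, 3] <- 0.1
  D3[5, 6] <- D3[6, 5] <- 0.1
  dimnames(D3) <- list(letters[1:6], letters[1:6])
  D4 <- matrix(1, 6, 6); diag(D4) <- 0
  D4[1, 2] <- D4[2, 1] <- 0.1   # shared pair
  D4[3, 5] <- D4[5, 3] <- 0.1   # recombined pairs
  D4[4, 6] <- D4[6, 4] <- 0.1
  dimnames(D4) <- list(letters[1:6], letters[1:6])
  half <- cluster_pairing_export(average_linkage(D3), average_linkage(D4))
  expect_equal(mean(half$agree), 1 / 3, tolerance = 1e-12)
})

test_that("the adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(97)
  for (i in 1:5) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(scovnet:::.adjusted_rand(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(scovnet:::.adjusted_rand(rep(1:3, 5), rep(c(7, 8, 9), 5)),
               1)
})

test_that("dendrograms serialize to Newick and JSON", {
  D <- as.matrix(dist(matrix(rnorm(5 * 3), 5)))
  dimnames(D) <- list(paste0("L", 1:5), paste0("L", 1:5))
  hc <- average_linkage(D)
  nwk <- dend_to_newick(hc)
  expect_match(nwk, "^\\(.*\\);$")
  tf <- tempfile(fileext = ".json")
  dend_to_json(hc, tf)
  parsed <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(parsed$labels, hc$labels)
  expect_equal(parsed$height, hc$height, tolerance = 1e-12)
})
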