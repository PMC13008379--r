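# Synthetic multisite cohort generator: covariance construction, edge
# implantation with PSD repair, sampling fidelity, severity link.

test_that("build_base_covariance constructs forced block structures", {
  C <- build_base_covariance(4, list(c(4, 0.3)))
  expect_equal(diag(C), rep(1, 4), ignore_attr = TRUE)
  expect_equal(C[upper.tri(C)], rep(0.3, 6))

  I <- build_base_covariance(3, list(c(1, 0), c(1, 0), c(1, 0)))
  expect_equal(unclass(I), diag(3), ignore_attr = TRUE)

  expect_error(build_base_covariance(5, list(c(4, 0.3))), "sum")
  expect_error(build_base_covariance(4, list(c(4, 1.2))), "within_r")
})

test_that("jittered base covariance is PSD by eigendecomposition oracle", {
  C <- build_base_covariance(30, list(c(10, 0.5), c(20, 0.2)),
                             seed = 7, jitter_sd = 0.2)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(diag(C), rep(1, 30), ignore_attr = TRUE)
  expect_identical(C, build_base_covariance(30, list(c(10, 0.5), c(20, 0.2)),
                                            seed = 7, jitter_sd = 0.2))
})

test_that("implant_edge_effects shifts entries and repairs PSD", {
  I4 <- diag(4); dimnames(I4) <- list(paste0("R", 1:4), paste0("R", 1:4))
  same <- implant_edge_effects(I4, data.frame(i = 1, j = 2, delta = 0))
  expect_equal(unclass(same), I4, ignore_attr = TRUE)

  one <- implant_edge_effects(I4, data.frame(i = 1, j = 2, delta = 0.2))
  expect_equal(one[1, 2], 0.2)
  expect_equal(one[2, 1], 0.2)
  expect_equal(one[3, 4], 0)
  expect_equal(attr(one, "repair_drift"), 0)

  expect_error(
    implant_edge_effects(I4, data.frame(i = 1, j = 2, delta = 1.5)),
    "\\(1, 2\\)")
})

test_that("dense effects forcing non-PSD are repaired near the clip projection", {
  # pairwise 0.9 among mutually uncorrelated regions is not PSD
  I5 <- diag(5)
  eff <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                    delta = c(0.9, 0.9, -0.9))
  out <- implant_edge_effects(I5, eff)
  expect_gte(min(eigen(out, symmetric = TRUE)$values), -1e-8)
  # independent projection oracle: clip eigenvalues, renormalize diagonal
  raw <- I5
  raw[1, 2] <- raw[2, 1] <- 0.9
  raw[1, 3] <- raw[3, 1] <- 0.9
  raw[2, 3] <- raw[3, 2] <- -0.9
  e <- eigen(raw, symmetric = TRUE)
  proj <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
  proj <- proj / tcrossprod(sqrt(diag(proj)))
  expect_equal(unname(unclass(out)), unname(proj), tolerance = 1e-10,
               ignore_attr = TRUE)
  drift <- attr(out, "repair_drift")
  expect_gt(drift, 0)
  expect_equal(max(abs(out - raw)), drift, tolerance = 1e-12)
})

test_that("empty cohort returns the full column schema", {
  g <- generate_cohort(cohort_spec(0, 0, region_labels = c("A", "B")))
  expect_equal(nrow(g$table), 0)
  expect_named(g$table, c("subject_id", "site", "group", "age", "sex",
                          "icv", "severity", "A", "B"))
})

test_that("sampling is bitwise-reproducible from the seed", {
  spec <- cohort_spec(15, 15, seed = 9, site_labels = c("a", "b"),
                      severity_link = list(i = 1, j = 2, r = 0.3))
  expect_identical(generate_cohort(spec), generate_cohort(spec))
})

test_that("implanted edge correlation is recovered at large n", {
  labs <- paste0("R", 1:6)
  spec <- cohort_spec(0, 20000, region_labels = labs,
                      base_covariance = diag(6) |>
                        `dimnames<-`(list(labs, labs)),
                      case_edge_effects = data.frame(i = 1, j = 2,
                                                     delta = 0.5),
                      seed = 11)
  g <- generate_cohort(spec)
  r <- cor(g$table$R1, g$table$R2)
  expect_lt(abs(r - 0.5), 0.02)
})

test_that("site shifts land on the site means", {
  labs <- paste0("R", 1:4)
  spec <- cohort_spec(400, 0, region_labels = labs,
                      base_covariance = diag(4) |>
                        `dimnames<-`(list(labs, labs)),
                      site_labels = c("s1", "s2"),
                      site_effects = list(s2 = list(shift = 10)),
                      region_sd = 1, seed = 5)
  tab <- generate_cohort(spec)$table
  d <- mean(tab$R1[tab$site == "s2"]) - mean(tab$R1[tab$site == "s1"])
  se <- sqrt(1 / sum(tab$site == "s1") + 1 / sum(tab$site == "s2"))
  expect_lt(abs(d - 10), 2 * se + 0.2)
})

test_that("severity map clamps, degenerates, and tracks the latent", {
  expect_equal(generate_severity(rnorm(10), link = 0, noise_sd = 0),
               rep(0.5, 10))
  s <- generate_severity(rnorm(200, sd = 50), link = 1, noise_sd = 5,
                         seed = 2)
  expect_gte(min(s), 0)
  expect_lte(max(s), 1)
  set.seed(3)
  lat <- rnorm(500)
  s2 <- generate_severity(lat, link = 1, noise_sd = 0.05, seed = 4)
  expect_gte(cor(lat, s2), 0.9)
})

test_that("null cohorts have matching group covariances and truth is recoverable", {
  labs <- paste0("R", 1:8)
  base <- build_base_covariance(8, list(c(4, 0.4), c(4, 0.4)))
  dimnames(base) <- list(labs, labs)
  spec <- cohort_spec(10000, 10000, region_labels = labs,
                      base_covariance = base, seed = 13)
  g <- generate_cohort(spec)
  Y <- as.matrix(g$table[, labs])
  dr <- cor(Y[g$table$group == "case", ]) -
        cor(Y[g$table$group == "control", ])
  expect_lt(max(abs(dr)), 0.05)
  expect_equal(nrow(g$truth$perturbed_edges), 0)

  spec2 <- cohort_spec(50, 50, region_labels = labs,
                       base_covariance = base,
                       case_edge_effects = data.frame(
                         i = c(1, 5), j = c(6, 8), delta = c(0.2, -0.15)),
                       seed = 14)
  tr <- generate_cohort(spec2)$truth
  dmat <- tr$case_cov - tr$control_cov
  idx <- which(abs(dmat) > 1e-12 & upper.tri(dmat), arr.ind = TRUE)
  expect_setequal(paste(tr$perturbed_edges$i, tr$perturbed_edges$j),
                  paste(idx[, 1], idx[, 2]))
  expect_setequal(round(tr$perturbed_edges$delta, 10),
                  round(dmat[idx], 10))
})
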