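# Template network perturbation: perturbed networks, Z standardization,
# altered-edge calling, profiles, severity associations.

test_that("perturbed_scn equals brute-force correlation over n + 1 rows", {
  ctrl <- toy_residuals(5, 4, seed = 81)
  subj <- toy_residuals(1, 4, seed = 82)
  net <- perturbed_scn(ctrl, subj, paste0("R", 1:4))
  W <- cor_matrix_oracle(rbind(as.matrix(ctrl), as.matrix(subj)))
  diag(W) <- NA
  expect_equal(net$weights, W, tolerance = 1e-12)
  expect_equal(net$n_subjects, 6)
  expect_error(perturbed_scn(ctrl[0, ], subj, paste0("R", 1:4)),
               "4 control")
})

test_that("adding a copy of an existing control barely moves the network", {
  set.seed(83)
  ctrl <- as.data.frame(matrix(rnorm(500 * 6), 500,
                               dimnames = list(NULL, paste0("R", 1:6))))
  net0 <- build_scn(ctrl, paste0("R", 1:6))
  net1 <- perturbed_scn(ctrl, ctrl[1, ], paste0("R", 1:6))
  expect_lt(max(abs(net1$weights - net0$weights), na.rm = TRUE), 0.01)
})

test_that("idscn_z applies both standardizations as stated", {
  d <- matrix(c(NA, 0.05, 0.05, NA), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  r <- matrix(c(NA, 0.5, 0.5, NA), 2, 2, dimnames = dimnames(d))
  zp <- idscn_z(d, r, n = 401, variant = "printed")
  expect_equal(zp["A", "B"], 0.05 / ((1 - 0.25) / 400))
  expect_equal(zp["A", "B"], 26.66667, tolerance = 1e-6)
  zs <- idscn_z(d, r, n = 401, variant = "sqrt")
  expect_equal(zs["A", "B"], 0.05 / ((1 - 0.25) / 20))
  expect_equal(zp["A", "B"] / zs["A", "B"], 20)

  d0 <- d; d0[] <- 0
  expect_equal(idscn_z(d0, r, 401)[1, 2], 0)
  expect_error(idscn_z(d, r, n = 3), ">= 4")
  rsat <- r; rsat[1, 2] <- rsat[2, 1] <- 1
  expect_true(is.nan(idscn_z(d, rsat, 401)[1, 2]))
})

test_that("altered-edge calling follows BH over the edge family", {
  Z <- matrix(0, 6, 6, dimnames = list(paste0("R", 1:6), paste0("R", 1:6)))
  diag(Z) <- NA
  expect_equal(call_altered_edges(Z)$n_altered, 0)

  set.seed(84)
  Z[upper.tri(Z)] <- rnorm(15, 0, 0.5)
  Z[1, 2] <- 12
  Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
  called <- call_altered_edges(Z, q = 0.05)
  expect_true(called$altered["R1", "R2"])
  expect_equal(called$n_altered, 1)
  # BH oracle on the constructed p vector
  p <- 2 * pnorm(-abs(Z[upper.tri(Z)]))
  p[p == 0] <- .Machine$double.xmin
  expect_equal(called$p_fdr[upper.tri(Z)], bh_oracle(p))
})

test_that("altered-edge profiles obey the counting identities", {
  fake <- function(id, edges, labs = paste0("R", 1:5)) {
    A <- matrix(FALSE, 5, 5, dimnames = list(labs, labs))
    for (e in edges) A[e[1], e[2]] <- A[e[2], e[1]] <- TRUE
    diag(A) <- NA
    list(subject_id = id, altered = A)
  }
  prof <- altered_edge_profile(list(
    fake("a", list()),
    fake("b", list(c(1, 2), c(1, 3), c(1, 4)))))
  expect_equal(prof$total_altered, c(0, 3))
  expect_equal(prof$R1[2], 3)
  expect_equal(sum(prof[2, paste0("R", 1:5)]), 2 * prof$total_altered[2])

  # bipartite: A-side counts sum to the total
  labs <- c("T1", "T2", "C1", "C2")
  A <- matrix(NA, 4, 4, dimnames = list(labs, labs))
  A["T1", c("C1", "C2")] <- A[c("C1", "C2"), "T1"] <- TRUE
  A["T2", c("C1", "C2")] <- A[c("C1", "C2"), "T2"] <- FALSE
  prof2 <- altered_edge_profile(list(list(subject_id = "x", altered = A)))
  expect_equal(prof2$total_altered, 2)
  expect_equal(prof2$T1 + prof2$T2, 2)
})

test_that("idscn_analysis is order-independent and additively consistent", {
  set.seed(85)
  labs <- paste0("R", 1:6)
  ctrl <- as.data.frame(matrix(rnorm(60 * 6), 60,
                               dimnames = list(NULL, labs)))
  cases <- as.data.frame(matrix(rnorm(4 * 6), 4,
                                dimnames = list(NULL, labs)))
  cases$subject_id <- paste0("k", 1:4)
  res <- idscn_analysis(ctrl, cases, labs)
  res_rev <- idscn_analysis(ctrl, cases[4:1, ], labs)
  expect_equal(res$results[[1]]$delta, res_rev$results[[4]]$delta)
  # Eq. 1: delta equals an independent recomputation of SCN_{n+1} - SCN_n
  Wn <- cor(as.matrix(ctrl)); diag(Wn) <- NA
  W1 <- cor(rbind(as.matrix(ctrl), as.matrix(cases[1, labs])))
  diag(W1) <- NA
  expect_equal(res$results[[1]]$delta, W1 - Wn, tolerance = 1e-14)
})

test_that("the perturbation shrinks with control-group size", {
  labs <- paste0("R", 1:8)
  C <- build_base_covariance(8, list(c(8, 0.3)))
  dimnames(C) <- list(labs, labs)
  cal <- idscn_null_calibration(C, n_values = c(50, 200, 800),
                                n_probe = 40, seed = 6)
  expect_true(all(diff(cal$median_max_abs_delta) < 0))
  # printed variant scales like sqrt(n) times the sqrt variant
  expect_equal(cal$z_sd_printed / cal$z_sd_sqrt,
               sqrt(cal$n - 1), tolerance = 0.01)
})

test_that("severity associations recover exact and null relationships", {
  set.seed(86)
  sev <- runif(50)
  out <- severity_association(2 * sev + 1, sev)
  expect_equal(out$r, 1, tolerance = 1e-12)

  # matches cor.test on noisy data
  x <- sev + rnorm(50, 0, 0.3)
  out2 <- severity_association(x, sev)
  ref <- cor.test(x, sev)
  expect_equal(out2$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(out2$p, ref$p.value, tolerance = 1e-12)

  expect_error(severity_association(rep(1, 50), sev), "zero-variance")
  expect_error(severity_association(x[1:5], sev[1:5]), "10 subjects")

  # adjusted regression keeps direction and magnitude
  age <- rnorm(50, 40, 10)
  y <- 3 * sev + 0.1 * age + rnorm(50, 0, 0.2)
  adj <- severity_association(y, sev, adjust = data.frame(age = age,
                                                          age2 = age^2))
  expect_equal(adj$beta_adj, 3, tolerance = 0.3)
  expect_lt(adj$p_adj, 0.001)
  fit <- lm(y ~ sev + age + I(age^2))
  expect_equal(adj$beta_adj, unname(coef(fit)["sev"]), tolerance = 1e-10)
})

test_that("independent features give calibrated severity tests", {
  set.seed(87)
  rej <- replicate(200, {
    sev <- runif(300)
    severity_association(rnorm(300), sev)$p < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("graded perturbations yield graded altered-edge counts", {
  labs <- paste0("R", 1:12)
  base <- diag(12); dimnames(base) <- list(labs, labs)
  eff <- expand.grid(i = 1:4, j = 5:8)
  eff$delta <- 0.6
  spec <- cohort_spec(200, 120, region_labels = labs,
                      base_covariance = base, case_edge_effects = eff,
                      perturb_grades = "uniform", seed = 19)
  g <- generate_cohort(spec)
  res <- idscn_analysis(g$table, g$table[g$table$group == "case", ],
                        labs)
  prof <- altered_edge_profile(res)
  rc <- cor(g$truth$perturb_grades, prof$total_altered,
            method = "spearman")
  expect_gt(rc, 0.5)
})
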