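# Individual differential SCNs via template network perturbation: one
# case subject is added to the control group, the control network is
# rebuilt, and the per-edge change is standardized, FDR-called, and
# related to symptom severity.

#' Perturbed control network for one subject
#'
#' Adds subject `k` to the `n` control subjects and rebuilds the
#' correlation network over the `n + 1` rows (the perturbed network).
#'
#' @param control_residuals data.frame/matrix of control-group region
#'   residuals.
#' @param subject a single-row data.frame (or named vector) holding the
#'   subject's values for every region in `nodes`.
#' @param nodes region columns.
#' @return an `scn` over `n + 1` subjects.
#' @export
perturbed_scn <- function(control_residuals, subject, nodes) {
  ctrl <- .region_cols(as.data.frame(control_residuals), nodes)
  if (nrow(ctrl) < 4) stop("need at least 4 control subjects")
  if (is.null(dim(subject))) subject <- as.data.frame(as.list(subject))
  row <- .region_cols(as.data.frame(subject), nodes)
  if (nrow(row) != 1) stop("subject must be a single row")
  W <- stats::cor(rbind(ctrl, row))
  net <- new_scn(W, group = "perturbed", n_subjects = nrow(ctrl) + 1L)
  net
}

#' Standardize an IDSCN perturbation matrix
#'
#' Converts the per-edge perturbation `delta = SCN_{n+1} - SCN_n` into a
#' Z matrix. The default (`"printed"`) form is
#' `Z = delta / ((1 - r_{n+1}^2) / (n - 1))` with `r_{n+1}` the perturbed
#' network's edge weight and `n` the control-group size; the `"sqrt"`
#' variant uses `(1 - r_{n+1}^2) / sqrt(n - 1)` as the scale, the form
#' found in the method literature. Edges with `|r_{n+1}| = 1` are flagged
#' non-finite and excluded from calling. The two variants differ by a
#' factor `sqrt(n - 1)` and their null behavior can be compared with
#' [idscn_null_calibration()].
#'
#' @param delta perturbation matrix (`NA` on absent edges).
#' @param perturbed the perturbed network (`scn`) or its weight matrix.
#' @param n control-group size (>= 4).
#' @param variant `"printed"` or `"sqrt"`.
#' @return Z matrix with the same mask as `delta`.
#' @export
idscn_z <- function(delta, perturbed, n, variant = c("printed", "sqrt")) {
  variant <- match.arg(variant)
  if (n < 4) stop("control-group size n must be >= 4")
  r <- if (inherits(perturbed, "scn")) perturbed$weights else perturbed
  denom <- if (variant == "printed") (1 - r^2) / (n - 1)
           else (1 - r^2) / sqrt(n - 1)
  z <- delta / denom
  z[is.finite(delta) & abs(r) >= 1 - 1e-12] <- NaN
  z[is.finite(delta) & delta == 0] <- 0
  z
}

#' Call altered edges from a Z matrix
#'
#' Two-sided standard-normal p per edge, BH-corrected across all present
#' edges of the (sub)network; altered edges are those with
#' `p_fdr < q`. Non-finite Z entries are excluded.
#'
#' @param Z matrix from [idscn_z()].
#' @param q FDR level (default 0.05).
#' @return list: `altered` (logical matrix), `p` and `p_fdr` matrices,
#'   `n_altered`.
#' @export
call_altered_edges <- function(Z, q = 0.05) {
  ut <- upper.tri(Z)
  idx <- which(ut & is.finite(Z))
  p <- 2 * stats::pnorm(-abs(Z[idx]))
  p[p == 0] <- .Machine$double.xmin
  pf <- bh_fdr(p, family = "idscn_edges")
  P <- PF <- matrix(NA_real_, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  A <- matrix(NA, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  P[idx] <- p; PF[idx] <- pf; A[idx] <- pf < q
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  PF[lower.tri(PF)] <- t(PF)[lower.tri(PF)]
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  list(altered = A, p = P, p_fdr = PF,
       n_altered = sum(A[ut], na.rm = TRUE))
}

#' Individual differential SCN analysis
#'
#' For each case subject, computes the perturbed network, the
#' perturbation matrix `IDSCN_k = SCN_{n+1} - SCN_n`, its Z matrix, and
#' the FDR-called altered-edge set.
#'
#' @param controls control-group ResidualTable (rows with
#'   `group == "control"` are used when a `group` column is present).
#' @param cases case-group ResidualTable (one IDSCN per row).
#' @param nodes region columns.
#' @param setA,setB optional bipartite partition applied to every matrix.
#' @param q FDR level for altered-edge calling.
#' @param z_variant see [idscn_z()].
#' @return object of class `idscn_set`: list with `template` (SCN_n),
#'   `results` (per-subject list: `subject_id`, `delta`, `z`, `p_fdr`,
#'   `altered`, `n_altered`), `n` (control size), `nodes`.
#' @export
idscn_analysis <- function(controls, cases, nodes, setA = NULL,
                           setB = NULL, q = 0.05,
                           z_variant = c("printed", "sqrt")) {
  z_variant <- match.arg(z_variant)
  cdf <- as.data.frame(controls)
  if ("group" %in% names(cdf) && any(cdf$group == "control"))
    cdf <- cdf[cdf$group == "control", , drop = FALSE]
  xdf <- as.data.frame(cases)
  ctrl <- .region_cols(cdf, nodes)
  n <- nrow(ctrl)
  if (n < 4) stop("need at least 4 control subjects")
  mask_na <- function(W) {
    diag(W) <- NA
    if (!is.null(setA)) {
      ia <- nodes %in% setA
      W[ia, ia] <- NA
      W[!ia, !ia] <- NA
    }
    W
  }
  Wn <- mask_na(stats::cor(ctrl))
  X <- .region_cols(xdf, nodes)
  ids <- if ("subject_id" %in% names(xdf)) xdf$subject_id
         else sprintf("case%04d", seq_len(nrow(X)))
  results <- vector("list", nrow(X))
  for (k in seq_len(nrow(X))) {
    Wk <- mask_na(stats::cor(rbind(ctrl, X[k, , drop = FALSE])))
    delta <- Wk - Wn
    z <- idscn_z(delta, Wk, n, variant = z_variant)
    called <- call_altered_edges(z, q = q)
    results[[k]] <- list(subject_id = ids[k], delta = delta, z = z,
                         p_fdr = called$p_fdr, altered = called$altered,
                         n_altered = called$n_altered)
  }
  structure(list(template = Wn, results = results, n = n, nodes = nodes,
                 setA = setA, q = q, z_variant = z_variant),
            class = "idscn_set")
}

#' Altered-edge profile across subjects
#'
#' Per-subject totals and per-node altered-edge counts. For a unipartite
#' network the per-node counts of one subject sum to twice that subject's
#' total (each edge touches two nodes); for a bipartite network the
#' counts over the A-side nodes sum to the total.
#'
#' @param idscn an `idscn_set` (or list of per-subject results sharing
#'   one network mask).
#' @return data.frame: `subject_id`, `total_altered`, one count column
#'   per node.
#' @export
altered_edge_profile <- function(idscn) {
  results <- if (inherits(idscn, "idscn_set")) idscn$results else idscn
  nodes <- colnames(results[[1]]$altered)
  mask0 <- is.na(results[[1]]$altered)
  rows <- lapply(results, function(r) {
    if (!identical(is.na(r$altered), mask0))
      stop("network masks differ across subjects")
    A <- r$altered
    per_node <- rowSums(A, na.rm = TRUE)
    c(total = sum(A[upper.tri(A)], na.rm = TRUE), per_node)
  })
  M <- do.call(rbind, rows)
  out <- data.frame(subject_id = vapply(results, `[[`, "",
                                        "subject_id"),
                    total_altered = M[, "total"])
  out[nodes] <- M[, nodes, drop = FALSE]
  out
}

#' Matrix of per-subject edge Z values
#'
#' Stacks each subject's Z (or raw delta) entries for the present edges
#' into a subjects-by-edges matrix for association testing. Edge columns
#' are named `"i|j"`.
#'
#' @param idscn an `idscn_set`.
#' @param what `"z"` or `"delta"`.
#' @return numeric matrix, rownames = subject ids.
#' @export
idscn_edge_matrix <- function(idscn, what = c("z", "delta")) {
  what <- match.arg(what)
  tmpl <- idscn$template
  idx <- which(upper.tri(tmpl) & is.finite(tmpl), arr.ind = TRUE)
  nodes <- colnames(tmpl)
  M <- t(vapply(idscn$results, function(r) r[[what]][idx],
                numeric(nrow(idx))))
  dimnames(M) <- list(vapply(idscn$results, `[[`, "", "subject_id"),
                      paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "|"))
  M
}

#' Associate IDSCN features with symptom severity
#'
#' Pearson correlation (two-sided) between a per-subject feature
#' (altered-edge counts or edge Z values) and severity, BH-corrected
#' across the supplied feature family. When covariates are supplied the
#' association is additionally estimated as the severity coefficient of a
#' multiple linear regression of the feature on severity plus covariates.
#'
#' @param values numeric vector, or subjects-by-features matrix.
#' @param severity unit-interval severity scores, one per subject.
#' @param adjust optional data.frame of covariates (e.g. sex, age, age^2)
#'   aligned with `values`.
#' @return data.frame: `feature`, `r`, `p`, `p_fdr`, and (with `adjust`)
#'   `beta_adj`, `p_adj`.
#' @export
severity_association <- function(values, severity, adjust = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1,
                                             dimnames = list(NULL, "value"))
  if (nrow(values) < 10) stop("need at least 10 subjects")
  if (any(!is.finite(severity))) stop("severity must be finite")
  if (stats::sd(severity) == 0) stop("severity has zero variance")
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(values)[sds == 0], collapse = ", "))
  r <- as.numeric(stats::cor(values, severity))
  nn <- nrow(values)
  tt <- r * sqrt((nn - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = nn - 2)
  p[p == 0] <- .Machine$double.xmin
  out <- data.frame(feature = colnames(values), r = r, p = p,
                    p_fdr = bh_fdr(p, family = "severity"))
  if (!is.null(adjust)) {
    X <- stats::model.matrix(~ ., data = cbind(severity = severity,
                                               as.data.frame(adjust)))
    out$beta_adj <- NA_real_
    out$p_adj <- NA_real_
    for (jcol in seq_len(ncol(values))) {
      fit <- stats::lm.fit(X, values[, jcol])
      rss <- sum(fit$residuals^2)
      df <- nn - fit$rank
      se <- sqrt(diag(chol2inv(fit$qr$qr[seq_len(fit$rank),
                                         seq_len(fit$rank)])) *
                   rss / df)
      bi <- match("severity", colnames(X))
      out$beta_adj[jcol] <- fit$coefficients[bi]
      out$p_adj[jcol] <- 2 * stats::pt(-abs(fit$coefficients[bi] / se[bi]),
                                       df = df)
    }
  }
  out
}

#' Null calibration of the IDSCN Z variants
#'
#' Simulates reference control groups and probe subjects from one
#' multivariate-normal control distribution, computes each probe's
#' perturbation matrix and both Z standardizations, and reports, per
#' control-group size: the median maximum absolute perturbation (which
#' should shrink as `n` grows) and the empirical SD of the Z entries
#' under the null for each variant.
#'
#' @param cov control correlation matrix (with dimnames).
#' @param n_values control-group sizes to probe.
#' @param n_probe probe subjects per size.
#' @param seed integer seed.
#' @return data.frame: `n`, `median_max_abs_delta`, `z_sd_printed`,
#'   `z_sd_sqrt`.
#' @export
idscn_null_calibration <- function(cov, n_values = c(50, 200, 800),
                                   n_probe = 100, seed = 1L) {
  labs <- colnames(cov)
  rows <- lapply(seq_along(n_values), function(g) {
    n <- n_values[g]
    set.seed(derive_seed(seed, g))
    ctrl <- .rmvn(n, cov)
    colnames(ctrl) <- labs
    Wn <- stats::cor(ctrl); diag(Wn) <- NA
    probes <- .rmvn(n_probe, cov)
    maxd <- numeric(n_probe)
    zp <- zs <- NULL
    for (k in seq_len(n_probe)) {
      Wk <- stats::cor(rbind(ctrl, probes[k, , drop = FALSE]))
      diag(Wk) <- NA
      delta <- Wk - Wn
      maxd[k] <- max(abs(delta), na.rm = TRUE)
      ut <- upper.tri(delta)
      zp <- c(zp, idscn_z(delta, Wk, n, "printed")[ut])
      zs <- c(zs, idscn_z(delta, Wk, n, "sqrt")[ut])
    }
    data.frame(n = n, median_max_abs_delta = stats::median(maxd),
               z_sd_printed = stats::sd(zp, na.rm = TRUE),
               z_sd_sqrt = stats::sd(zs, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
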