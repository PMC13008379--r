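# Synthetic multisite cohort generator with known ground truth.
#
# Volumes are drawn per group from a multivariate normal with a specified
# correlation structure, then distorted by site-wise affine (scale/shift)
# batch effects and additive covariate effects (age, age^2, sex, ICV), so
# that every downstream stage (harmonization, residualization, SCN
# comparison, IDSCN, clustering) has a recoverable implanted target.

#' Derive a stage seed from a master seed
#'
#' All randomness in a simulated cohort flows from one spec-level seed;
#' per-stage seeds are derived deterministically so that stages are
#' individually reproducible.
#'
#' @param seed master integer seed.
#' @param stage small non-negative integer stage index.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stage)) %%
               2147483647)
}

#' Repair a symmetric matrix to the nearest correlation-like PSD matrix
#'
#' Eigenvalue clipping at zero followed by re-normalization to unit
#' diagonal. The maximum absolute entry displacement introduced by the
#' repair is attached as attribute `"repair_drift"`.
#'
#' @param x symmetric matrix with unit diagonal intended as a correlation
#'   matrix.
#' @param tol eigenvalues above `-tol` are considered numerically
#'   non-negative and trigger no repair.
#' @return repaired matrix with attribute `repair_drift`.
#' @export
psd_repair <- function(x, tol = 1e-8) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  if (max(abs(x - t(x))) > 1e-10)
    stop("psd_repair: input matrix is not symmetric")
  e <- eigen(x, symmetric = TRUE)
  if (min(e$values) >= -tol) {
    attr(x, "repair_drift") <- 0
    return(x)
  }
  lam <- pmax(e$values, 0)
  y <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(y))
  if (any(d <= 0))
    stop("psd_repair: zero diagonal after eigenvalue clipping")
  y <- y / tcrossprod(d)
  y <- (y + t(y)) / 2
  diag(y) <- 1
  dimnames(y) <- dimnames(x)
  attr(y, "repair_drift") <- max(abs(y - x))
  y
}

#' Build a block-structured base correlation matrix
#'
#' Constructs the control-group correlation structure as compound-symmetric
#' blocks (within-block correlation `within_r`, zero between blocks), with
#' optional symmetric jitter followed by PSD repair.
#'
#' @param n_regions total number of regions.
#' @param blocks list of `c(size, within_r)` pairs (or 2-column matrix);
#'   sizes must sum to `n_regions`, `0 <= within_r < 1`.
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @param jitter_sd standard deviation of symmetric off-diagonal jitter.
#' @return correlation matrix (unit diagonal, smallest eigenvalue
#'   >= -1e-8), with attribute `repair_drift`.
#' @export
build_base_covariance <- function(n_regions, blocks, seed = 1L,
                                  jitter_sd = 0) {
  if (is.matrix(blocks)) blocks <- lapply(seq_len(nrow(blocks)),
                                          function(i) blocks[i, ])
  sizes <- vapply(blocks, function(b) b[[1]], numeric(1))
  rs <- vapply(blocks, function(b) b[[2]], numeric(1))
  if (any(rs < 0 | rs >= 1))
    stop("build_base_covariance: within_r must be in [0, 1)")
  if (sum(sizes) != n_regions)
    stop("build_base_covariance: block sizes sum to ", sum(sizes),
         ", expected ", n_regions)
  C <- matrix(0, n_regions, n_regions)
  at <- 0L
  for (b in seq_along(sizes)) {
    idx <- at + seq_len(sizes[b])
    C[idx, idx] <- rs[b]
    at <- at + sizes[b]
  }
  diag(C) <- 1
  if (jitter_sd > 0) {
    set.seed(derive_seed(seed, 1L))
    J <- matrix(stats::rnorm(n_regions^2, 0, jitter_sd), n_regions)
    J <- (J + t(J)) / 2
    diag(J) <- 0
    C <- C + J
    C[C > 1] <- 1
    C[C < -1] <- -1
  }
  C <- psd_repair(C)
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("build_base_covariance: matrix not PSD after repair for blocks: ",
         paste(sprintf("(%d, %.3f)", sizes, rs), collapse = ", "))
  C
}

.normalize_effects <- function(effects, labels = NULL) {
  if (is.null(effects) || (is.data.frame(effects) && nrow(effects) == 0))
    return(data.frame(i = integer(), j = integer(), delta = numeric()))
  if (!is.data.frame(effects))
    effects <- do.call(rbind, lapply(effects, function(e)
      data.frame(i = e[[1]], j = e[[2]], delta = e[[3]])))
  names(effects)[1:3] <- c("i", "j", "delta")
  if (is.character(effects$i)) {
    effects$i <- match(effects$i, labels)
    effects$j <- match(effects$j, labels)
    if (anyNA(effects$i) || anyNA(effects$j))
      stop("edge effect references unknown region label")
  }
  effects
}

#' Implant edge-level correlation effects
#'
#' Shifts selected correlation entries by `delta_r` (symmetrically), then
#' repairs to the nearest PSD correlation matrix if the shifts broke
#' positive semi-definiteness. The repair displacement is reported via
#' attribute `repair_drift`.
#'
#' @param cov correlation matrix.
#' @param effects data.frame with columns `i`, `j`, `delta` (indices or
#'   region labels), or a list of `(i, j, delta)` triples.
#' @return shifted (and possibly repaired) correlation matrix.
#' @export
implant_edge_effects <- function(cov, effects) {
  eff <- .normalize_effects(effects, colnames(cov))
  out <- cov
  for (k in seq_len(nrow(eff))) {
    i <- eff$i[k]; j <- eff$j[k]
    v <- out[i, j] + eff$delta[k]
    if (abs(v) > 1)
      stop(sprintf(
        "implant_edge_effects: edge (%d, %d) leaves [-1, 1] (value %.3f)",
        i, j, v))
    out[i, j] <- out[j, i] <- v
  }
  psd_repair(out)
}

#' Specify a synthetic multisite cohort
#'
#' Collects everything the generator needs: group sizes, the control-group
#' correlation structure, case-specific edge effects, per-site batch
#' effects, covariate effects, an optional severity link, and a seed.
#'
#' @param n_control,n_case group sizes (>= 0).
#' @param region_labels region names; defaults to the 50 thalamic nuclei.
#' @param base_covariance control-group correlation matrix; defaults to a
#'   block structure over the regions.
#' @param case_edge_effects edge effects implanted into the case group
#'   (see [implant_edge_effects()]).
#' @param site_labels site names; subjects are assigned uniformly.
#' @param site_effects named list (per site) of `list(shift=, scale=)`,
#'   scalars or per-region vectors. Defaults to no site effects.
#' @param covariate_effects list with per-region (or scalar) entries
#'   `age_slope`, `age2`, `sex`, `icv`. Defaults to zeros.
#' @param severity_link `NULL`, or `list(i=, j=, r=)`: the correlation
#'   implanted between case severity and the subject's standardized
#'   deviation at edge `(i, j)`.
#' @param perturb_grades `NULL`, or `"uniform"` to give each case subject
#'   a graded perturbation multiplier in `[0, 1]` applied to the
#'   case-minus-control covariance difference.
#' @param noise_sd additive measurement noise SD (volume units).
#' @param region_mean,region_sd scalar or per-region volume location and
#'   scale in mm^3.
#' @param seed master integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control, n_case,
                        region_labels = thalamic_nuclei_labels(),
                        base_covariance = NULL,
                        case_edge_effects = NULL,
                        site_labels = "site1",
                        site_effects = NULL,
                        covariate_effects = NULL,
                        severity_link = NULL,
                        perturb_grades = NULL,
                        noise_sd = 0,
                        region_mean = 1000,
                        region_sd = 100,
                        seed = 1L) {
  p <- length(region_labels)
  if (n_control < 0 || n_case < 0) stop("group sizes must be >= 0")
  if (is.null(base_covariance)) {
    nb <- max(1L, p %/% 10L)
    sizes <- rep(p %/% nb, nb)
    sizes[1] <- sizes[1] + p - sum(sizes)
    base_covariance <- build_base_covariance(
      p, lapply(sizes, function(s) c(s, 0.3)))
  }
  stopifnot(nrow(base_covariance) == p)
  if (max(abs(base_covariance - t(base_covariance))) > 1e-10)
    stop("base_covariance must be symmetric")
  if (max(abs(diag(base_covariance) - 1)) > 1e-10)
    stop("base_covariance must have unit diagonal")
  if (min(eigen(base_covariance, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("base_covariance must be positive semi-definite")
  dimnames(base_covariance) <- list(region_labels, region_labels)
  ce <- list(age_slope = 0, age2 = 0, sex = 0, icv = 0)
  if (!is.null(covariate_effects)) ce[names(covariate_effects)] <-
      covariate_effects
  spec <- list(
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    region_labels = region_labels,
    base_covariance = base_covariance,
    case_edge_effects = .normalize_effects(case_edge_effects,
                                           region_labels),
    site_labels = site_labels, site_effects = site_effects,
    covariate_effects = ce,
    severity_link = severity_link,
    perturb_grades = perturb_grades,
    noise_sd = noise_sd,
    region_mean = rep_len(region_mean, p),
    region_sd = rep_len(region_sd, p),
    seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Map latent perturbation scores to unit-interval severity scores
#'
#' `score = clamp(center + scale * (link * latent + noise))`, or a logistic
#' map of the same linear predictor. With `link = 0`, `noise_sd = 0` all
#' scores equal `center`.
#'
#' @param latent numeric vector of per-subject latent perturbation scores.
#' @param link linear coefficient tying latent to severity.
#' @param noise_sd SD of additive noise on the linear predictor.
#' @param seed integer seed.
#' @param map `"linear"` (clamped) or `"logistic"`.
#' @param center,scale location and gain of the map.
#' @return severity scores in `[0, 1]`.
#' @export
generate_severity <- function(latent, link, noise_sd, seed = 1L,
                              map = c("linear", "logistic"),
                              center = 0.5, scale = 0.15) {
  map <- match.arg(map)
  if (any(!is.finite(latent))) stop("latent scores must be finite")
  set.seed(seed)
  lin <- link * latent + stats::rnorm(length(latent), 0, noise_sd)
  s <- if (map == "linear") center + scale * lin
       else stats::plogis(4 * scale * lin + stats::qlogis(center))
  pmin(1, pmax(0, s))
}

# Sample n rows of standard MVN deviates with correlation C (via Cholesky
# with a PSD fallback through the eigendecomposition).
.rmvn <- function(n, C) {
  p <- ncol(C)
  Z <- matrix(stats::rnorm(n * p), n, p)
  L <- tryCatch(chol(C), error = function(e) {
    e2 <- eigen(C, symmetric = TRUE)
    t(e2$vectors %*% (sqrt(pmax(e2$values, 0)) * t(e2$vectors)))
  })
  Z %*% L
}

#' Generate a synthetic multisite cohort
#'
#' Draws per-subject standardized volumes from the group-specific
#' multivariate normal, converts them to mm^3 volumes, applies site-wise
#' affine batch effects and covariate effects, and attaches demographic
#' metadata and severity scores. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return `list(table = FeatureTable data.frame, truth = ground-truth
#'   list)`. The truth carries both group covariance matrices, the
#'   implanted perturbed-edge list, per-subject latent perturbation scores,
#'   and the site/covariate effect values.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- length(spec$region_labels)
  ctrl_cov <- spec$base_covariance
  case_cov <- implant_edge_effects(ctrl_cov, spec$case_edge_effects)
  for (C in list(ctrl_cov, case_cov))
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("degenerate covariance; refusing to sample")
  n <- spec$n_control + spec$n_case
  group <- rep(c("control", "case"), c(spec$n_control, spec$n_case))

  empty <- data.frame(subject_id = character(), site = character(),
                      group = character(), age = numeric(),
                      sex = integer(), icv = numeric(),
                      severity = numeric())
  for (r in spec$region_labels) empty[[r]] <- numeric()

  delta_true <- case_cov - ctrl_cov
  ut <- upper.tri(delta_true)
  hit <- which(abs(delta_true) > 1e-12 & ut, arr.ind = TRUE)
  perturbed <- data.frame(
    i = hit[, 1], j = hit[, 2],
    label_i = spec$region_labels[hit[, 1]],
    label_j = spec$region_labels[hit[, 2]],
    delta = delta_true[hit])

  truth <- list(control_cov = ctrl_cov, case_cov = case_cov,
                perturbed_edges = perturbed,
                latent = numeric(0), perturb_grades = NULL,
                site_effects = spec$site_effects,
                covariate_effects = spec$covariate_effects)
  if (n == 0) return(list(table = empty, truth = truth))

  set.seed(derive_seed(spec$seed, 2L))
  age <- pmin(75, pmax(18, stats::rnorm(n, 40, 12)))
  sex <- stats::rbinom(n, 1, 0.5)
  icv <- stats::rnorm(n, 1.45e6, 1.4e5)
  site <- sample(spec$site_labels, n, replace = TRUE)

  set.seed(derive_seed(spec$seed, 3L))
  Z <- matrix(0, n, p)
  is_ctrl <- group == "control"
  if (any(is_ctrl)) Z[is_ctrl, ] <- .rmvn(sum(is_ctrl), ctrl_cov)
  grades <- NULL
  if (any(!is_ctrl)) {
    if (is.null(spec$perturb_grades)) {
      Z[!is_ctrl, ] <- .rmvn(sum(!is_ctrl), case_cov)
    } else {
      # graded perturbation: subject covariance is the convex combination
      # control + m_k * (case - control), m_k in [0, 1] (PSD by
      # convexity), and the subject's deviation amplitude is scaled by
      # (1 + m_k) -- a subject's influence on a correlation grows with
      # its leverage, so graded network perturbation requires graded
      # distance from the control centroid, not only a graded pattern
      nc <- sum(!is_ctrl)
      grades <- stats::runif(nc)
      rows <- which(!is_ctrl)
      for (k in seq_len(nc)) {
        Ck <- ctrl_cov + grades[k] * (case_cov - ctrl_cov)
        Z[rows[k], ] <- (1 + grades[k]) * .rmvn(1, Ck)
      }
      truth$perturb_grades <- grades
    }
  }

  # latent perturbation score: standardized cross-deviation at the linked
  # edge -- the quantity the IDSCN delta of that edge measures
  latent <- rep(0, n)
  if (!is.null(spec$severity_link) && any(!is_ctrl)) {
    li <- spec$severity_link$i; lj <- spec$severity_link$j
    if (is.character(li)) li <- match(li, spec$region_labels)
    if (is.character(lj)) lj <- match(lj, spec$region_labels)
    cross <- Z[, li] * Z[, lj] - case_cov[li, lj]
    latent[!is_ctrl] <- scale(cross[!is_ctrl])[, 1]
  }

  severity <- numeric(n)
  sev_seed <- derive_seed(spec$seed, 4L)
  if (!is.null(spec$severity_link)) {
    r_link <- spec$severity_link$r
    severity[!is_ctrl] <- generate_severity(
      latent[!is_ctrl], link = r_link,
      noise_sd = sqrt(max(0, 1 - r_link^2)), seed = sev_seed)
  } else {
    set.seed(sev_seed)
    severity[!is_ctrl] <- pmin(1, pmax(0, stats::rnorm(sum(!is_ctrl),
                                                       0.5, 0.15)))
  }
  set.seed(derive_seed(spec$seed, 5L))
  severity[is_ctrl] <- pmin(1, pmax(0, stats::rnorm(sum(is_ctrl),
                                                    0.1, 0.07)))

  vol <- sweep(sweep(Z, 2, spec$region_sd, `*`), 2, spec$region_mean, `+`)
  if (spec$noise_sd > 0) {
    set.seed(derive_seed(spec$seed, 6L))
    vol <- vol + matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
  }

  ce <- spec$covariate_effects
  a0 <- age - 40
  vol <- vol +
    outer(a0, rep_len(ce$age_slope, p)) +
    outer(a0^2, rep_len(ce$age2, p)) +
    outer(sex, rep_len(ce$sex, p)) +
    outer(icv - 1.45e6, rep_len(ce$icv, p))

  if (!is.null(spec$site_effects)) {
    for (s in names(spec$site_effects)) {
      rows <- site == s
      if (!any(rows)) next
      eff <- spec$site_effects[[s]]
      sc <- rep_len(if (is.null(eff$scale)) 1 else eff$scale, p)
      sh <- rep_len(if (is.null(eff$shift)) 0 else eff$shift, p)
      vol[rows, ] <- sweep(sweep(vol[rows, , drop = FALSE], 2, sc, `*`),
                           2, sh, `+`)
    }
  }

  colnames(vol) <- spec$region_labels
  tab <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    site = site, group = group, age = age, sex = sex, icv = icv,
    severity = severity, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(vol))
  truth$latent <- stats::setNames(latent, tab$subject_id)
  list(table = tab, truth = truth)
}
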