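# Data preparation: outlier screening, site harmonization, covariate
# residualization, severity normalization.

.region_cols <- function(table, regions) {
  miss <- setdiff(regions, names(table))
  if (length(miss))
    stop("missing region columns: ", paste(miss, collapse = ", "))
  as.matrix(table[, regions, drop = FALSE])
}

#' Remove volumetric outlier subjects
#'
#' A subject is removed iff any region volume deviates from the
#' full-sample mean of that region by more than `z_threshold` sample
#' standard deviations. Reference statistics are computed once on the full
#' pooled sample (single pass), so screening is idempotent given those
#' statistics. The default threshold of 2.698 SD corresponds to the
#' conventional 3x interquartile-range rule under normality.
#'
#' @param table FeatureTable data.frame.
#' @param regions region columns to screen (per network analysis).
#' @param z_threshold positive deviation threshold in SD units.
#' @return `list(table = retained rows, removed = removed subject ids,
#'   n_removed)`.
#' @export
remove_outliers <- function(table, regions, z_threshold = 2.698) {
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  if (nrow(table) < 3) stop("need at least 3 subjects")
  Y <- .region_cols(table, regions)
  mu <- colMeans(Y)
  sd <- apply(Y, 2, stats::sd)
  Zs <- abs(sweep(sweep(Y, 2, mu), 2, pmax(sd, .Machine$double.eps), "/"))
  bad <- apply(Zs, 1, max) > z_threshold
  if (all(bad)) stop("outlier screening removed every subject")
  list(table = table[!bad, , drop = FALSE],
       removed = table$subject_id[bad],
       n_removed = sum(bad))
}

#' Harmonize region volumes across sites/scanners
#'
#' Empirical-Bayes location/scale batch adjustment (ComBat) removing
#' site-related variability while preserving variability explained by the
#' covariates of interest. The covariate basis is linear in sex, ICV and
#' group, with a polynomial age basis of configurable degree (degree 2 by
#' default, i.e. age and age^2) as a flexible stand-in for spline bases.
#'
#' @param table FeatureTable data.frame with a `site` column.
#' @param regions region columns to harmonize.
#' @param covariates metadata columns whose effects must be preserved.
#' @param age_basis_degree polynomial degree for the age basis.
#' @return the table with harmonized region columns.
#' @export
harmonize_sites <- function(table, regions,
                            covariates = c("age", "sex", "icv", "group"),
                            age_basis_degree = 2) {
  miss <- setdiff(c(covariates, "site"), names(table))
  if (length(miss))
    stop("missing covariate columns: ", paste(miss, collapse = ", "))
  site <- factor(table$site)
  if (nlevels(site) < 2) return(table)
  small <- names(which(table(site) < 2))
  if (length(small))
    stop("site(s) with fewer than 2 subjects: ",
         paste(small, collapse = ", "))
  Y <- .region_cols(table, regions)
  terms <- character(0)
  for (cv in covariates) {
    if (cv == "age" && age_basis_degree >= 1) {
      terms <- c(terms, "age",
                 if (age_basis_degree >= 2)
                   paste0("I(age^", 2:age_basis_degree, ")"))
    } else if (length(unique(table[[cv]])) < 2) {
      next  # constant covariate carries no preservable variation
    } else {
      terms <- c(terms, cv)
    }
  }
  if (!length(terms)) terms <- "1"
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  df <- table
  if ("group" %in% covariates) df$group <- factor(df$group)
  mod <- stats::model.matrix(fml, data = df)
  utils::capture.output(suppressMessages(
    adj <- t(sva::ComBat(dat = t(Y), batch = site, mod = mod,
                         par.prior = TRUE, prior.plots = FALSE))),
    type = "output")
  out <- table
  out[, regions] <- adj
  out
}

#' Residualize region volumes on nuisance covariates
#'
#' Per region, ordinary least squares of volume on
#' `[intercept, age, age^2, sex, ICV]`, fitted over all subjects pooled
#' (the default) or within each diagnostic group (`scope = "per_group"`,
#' the sensitivity mode). Returns the table with region columns replaced
#' by residuals; residual columns have mean (numerically) zero and are
#' orthogonal to every covariate column.
#'
#' @param table FeatureTable data.frame.
#' @param regions region columns to residualize.
#' @param scope `"pooled"` or `"per_group"`.
#' @param max_condition maximum allowed design-matrix condition number.
#' @return ResidualTable: the input table with residualized regions.
#' @export
residualize <- function(table, regions, scope = c("pooled", "per_group"),
                        max_condition = 1e10) {
  scope <- match.arg(scope)
  need <- c("age", "sex", "icv")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("missing covariate columns: ", paste(miss, collapse = ", "))
  fit_block <- function(tab) {
    Y <- .region_cols(tab, regions)
    X <- cbind(1, tab$age, tab$age^2, as.numeric(tab$sex), tab$icv)
    # scale columns for a fair conditioning check (ICV is ~1e6)
    Xs <- sweep(X, 2, pmax(apply(abs(X), 2, max), 1), "/")
    kap <- kappa(Xs, exact = TRUE)
    if (!is.finite(kap) || kap > max_condition)
      stop(sprintf(
        "collinear covariate design (condition number %.3g > %.3g)",
        kap, max_condition))
    qr.resid(qr(X), Y)
  }
  out <- table
  if (scope == "pooled") {
    out[, regions] <- fit_block(table)
  } else {
    for (g in unique(table$group)) {
      rows <- table$group == g
      out[rows, regions] <- fit_block(table[rows, , drop = FALSE])
    }
  }
  class(out) <- c("residual_table", class(table))
  out
}

#' Normalize a raw severity score to the unit interval
#'
#' `(raw - instrument_min) / (instrument_max - instrument_min)`, allowing
#' severity measures from different assessment instruments to be pooled.
#'
#' @param raw raw instrument score(s).
#' @param instrument_min,instrument_max instrument score range.
#' @return scores in `[0, 1]`.
#' @export
normalize_severity <- function(raw, instrument_min, instrument_max) {
  if (instrument_max <= instrument_min)
    stop("instrument_max must exceed instrument_min")
  if (any(raw < instrument_min | raw > instrument_max, na.rm = TRUE))
    stop("raw score outside the instrument range")
  (raw - instrument_min) / (instrument_max - instrument_min)
}
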