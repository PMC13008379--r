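# End-to-end orchestration: feature-table IO with schema validation,
# configuration handling, and the staged pipeline
# simulate -> preprocess -> SCN -> stats -> IDSCN -> clustering.

.REQUIRED_META <- c("subject_id", "site", "group", "age", "sex", "icv")

#' Read a feature table with schema validation
#'
#' Reads a delimited text file (separator inferred from the extension:
#' `.tsv`/`.txt` = tab, otherwise comma) and validates the schema:
#' required metadata columns, numeric parses for age/sex/ICV/severity and
#' every region column, and unique subject ids. All violations are
#' collected and reported together.
#'
#' @param path file path.
#' @param regions region columns that must be present and numeric;
#'   `NULL` means every non-metadata column is treated as a region.
#' @return validated FeatureTable data.frame.
#' @export
read_feature_table <- function(path, regions = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  errs <- character(0)
  miss <- setdiff(.REQUIRED_META, names(raw))
  if (length(miss))
    errs <- c(errs, paste0("missing required column(s): ",
                           paste(miss, collapse = ", ")))
  if (is.null(regions))
    regions <- setdiff(names(raw), c(.REQUIRED_META, "severity"))
  miss_r <- setdiff(regions, names(raw))
  if (length(miss_r))
    errs <- c(errs, paste0("missing region column(s): ",
                           paste(miss_r, collapse = ", ")))
  num_cols <- intersect(c("age", "sex", "icv", "severity", regions),
                        names(raw))
  out <- raw
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]) & nzchar(raw[[cl]]))
    if (length(bad))
      errs <- c(errs, sprintf(
        "non-numeric value in column '%s' at row(s) %s", cl,
        paste(utils::head(bad, 5), collapse = ", ")))
    out[[cl]] <- v
  }
  if ("subject_id" %in% names(out) && anyDuplicated(out$subject_id))
    errs <- c(errs, "duplicate subject_id values")
  if (length(errs))
    stop("feature table schema violations:\n  - ",
         paste(errs, collapse = "\n  - "))
  out
}

#' Write a feature table / ground truth
#'
#' @param table FeatureTable data.frame.
#' @param path output path (`.tsv` for tab, else comma).
#' @return the path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param truth ground-truth list from [generate_cohort()].
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Default run configuration
#'
#' Nested key/value configuration driving [run_pipeline()]; any subset of
#' keys can be overridden by the `config` argument or a YAML file.
#'
#' @return nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    input = NULL,
    simulate = list(n_control = 100L, n_case = 100L,
                    regions = "thalamic", sites = 1L,
                    case_strength_delta = 0, noise_sd = 0),
    outlier = list(z_threshold = 2.698),
    harmonize = list(enabled = TRUE, age_basis_degree = 2),
    residualize = list(scope = "pooled"),
    perm = list(n_graph = 5000L, n_edge = 100000L),
    fdr = list(q = 0.05),
    idscn = list(enabled = TRUE, z_variant = "printed"),
    cluster = list(enabled = TRUE, alpha = 1),
    sweep_step = 0.025)
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration from YAML
#'
#' @param path YAML file.
#' @return configuration list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  .merge_config(default_run_config(), yaml::read_yaml(path))
}

.network_defs <- function(cols) {
  thal <- intersect(thalamic_nuclei_labels(), cols)
  ctx <- intersect(dk_cortical_labels(), cols)
  sub <- intersect(subcortical_labels(), cols)
  defs <- list()
  if (length(thal) >= 4)
    defs$intrathalamic <- list(nodes = thal, setA = NULL, setB = NULL)
  if (length(thal) >= 4 && length(ctx) >= 2)
    defs$thalamocortical <- list(nodes = c(thal, ctx), setA = thal,
                                 setB = ctx)
  if (length(thal) >= 4 && length(sub) >= 2)
    defs$thalamosubcortical <- list(nodes = c(thal, sub), setA = thal,
                                    setB = sub)
  defs
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (or table ingestion), per-network
#' outlier screening, site harmonization, covariate residualization,
#' group SCN construction with threshold sweep, permutation statistics
#' (graph strength across the sweep, node strength, edge SC_diff),
#' IDSCN analysis with severity associations, and hierarchical
#' clustering of thalamic nuclei by SC_diff profile. All stage outputs
#' and a JSON run report are written under `out_dir`; identical config
#' and seed give identical outputs.
#'
#' @param config configuration list (see [default_run_config()]) or path
#'   to a YAML file.
#' @param out_dir output directory (created if absent).
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("scovnet_")) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- .merge_config(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    report$stages[[name]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 3))
    val
  }

  tab <- t_stage("input", {
    if (!is.null(cfg$input)) {
      read_feature_table(cfg$input)
    } else {
      sim <- cfg$simulate
      if (sim$n_case < 1 || sim$n_control < 1)
        stop("simulation requires nonempty case and control groups")
      regions <- switch(sim$regions,
                        thalamic = thalamic_nuclei_labels(),
                        all = c(thalamic_nuclei_labels(),
                                dk_cortical_labels(),
                                subcortical_labels()),
                        sim$regions)
      p <- length(regions)
      base <- build_base_covariance(
        p, list(c(p %/% 2, 0.3), c(p - p %/% 2, 0.3)))
      eff <- NULL
      if (sim$case_strength_delta != 0) {
        ut <- which(upper.tri(base) & base != 0, arr.ind = TRUE)
        eff <- data.frame(i = ut[, 1], j = ut[, 2],
                          delta = sim$case_strength_delta)
      }
      spec <- cohort_spec(
        n_control = sim$n_control, n_case = sim$n_case,
        region_labels = regions, base_covariance = base,
        case_edge_effects = eff,
        site_labels = paste0("site", seq_len(max(1L, sim$sites))),
        noise_sd = sim$noise_sd, seed = derive_seed(cfg$seed, 10L))
      gen <- generate_cohort(spec)
      write_ground_truth(gen$truth, file.path(out_dir, "ground_truth.json"))
      gen$table
    }
  })
  write_feature_table(tab, file.path(out_dir, "feature_table.csv"))
  report$n_subjects_input <- nrow(tab)

  defs <- .network_defs(names(tab))
  if (!length(defs)) stop("no analyzable network: too few region columns")
  removal_log <- list()
  results <- list()

  for (nw in names(defs)) {
    def <- defs[[nw]]
    scr <- t_stage(paste0("outlier_", nw),
                   remove_outliers(tab, def$nodes,
                                   cfg$outlier$z_threshold))
    removal_log[[nw]] <- list(n_removed = scr$n_removed,
                              removed = scr$removed)
    dat <- scr$table
    if (isTRUE(cfg$harmonize$enabled))
      dat <- t_stage(paste0("harmonize_", nw),
                     harmonize_sites(dat, def$nodes,
                                     age_basis_degree =
                                       cfg$harmonize$age_basis_degree))
    res <- t_stage(paste0("residualize_", nw),
                   residualize(dat, def$nodes,
                               scope = cfg$residualize$scope))

    nets <- t_stage(paste0("scn_", nw), {
      case <- build_scn(res, def$nodes, group = "case")
      ctrl <- build_scn(res, def$nodes, group = "control")
      if (!is.null(def$setA)) {
        case <- extract_bipartite(case, def$setA, def$setB)
        ctrl <- extract_bipartite(ctrl, def$setA, def$setB)
      }
      list(case = case, control = ctrl)
    })
    write_scn(nets$case, file.path(out_dir, paste0(nw, "_case.csv")))
    write_scn(nets$control, file.path(out_dir, paste0(nw, "_control.csv")))

    sweep <- threshold_sweep(nets$case, nets$control, cfg$sweep_step)
    stats_out <- t_stage(paste0("stats_", nw), {
      M <- res
      labels <- res$group
      gs <- permutation_test(
        M[, def$nodes, drop = FALSE], labels,
        stat_graph_strength(def$nodes, def$setA,
                            thresholds = c(list(NULL),
                                           as.list(sweep))),
        n_perm = cfg$perm$n_graph, seed = derive_seed(cfg$seed, 20L),
        family = paste0(nw, "_graph_strength"))
      ns <- permutation_test(
        M[, def$nodes, drop = FALSE], labels,
        stat_node_strength(def$nodes, def$setA),
        n_perm = cfg$perm$n_graph, seed = derive_seed(cfg$seed, 21L),
        family = paste0(nw, "_node_strength"))
      list(graph = gs, node = ns,
           sc_diff = sc_diff(nets$case, nets$control),
           sweep = sweep)
    })
    perm_test_table(stats_out$graph,
                    file.path(out_dir, paste0(nw, "_graph_strength.tsv")))
    perm_test_table(stats_out$node,
                    file.path(out_dir, paste0(nw, "_node_strength.tsv")))

    idscn_out <- NULL
    if (isTRUE(cfg$idscn$enabled)) {
      idscn_out <- t_stage(paste0("idscn_", nw), {
        set <- idscn_analysis(res[res$group == "control", ],
                              res[res$group == "case", ],
                              def$nodes, setA = def$setA,
                              setB = def$setB, q = cfg$fdr$q,
                              z_variant = cfg$idscn$z_variant)
        prof <- altered_edge_profile(set)
        assoc <- NULL
        sev <- res$severity[res$group == "case"]
        if (!is.null(sev) && stats::sd(sev) > 0 &&
            stats::sd(prof$total_altered) > 0) {
          assoc <- severity_association(prof$total_altered, sev)
          assoc$feature <- "total_altered"
        }
        list(set = set, profile = prof, assoc = assoc)
      })
      utils::write.table(idscn_out$profile,
                         file.path(out_dir, paste0(nw, "_idscn_profile.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (!is.null(idscn_out$assoc))
        utils::write.table(idscn_out$assoc,
                           file.path(out_dir,
                                     paste0(nw, "_severity_assoc.tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    results[[nw]] <- list(nets = nets, stats = stats_out,
                          idscn = idscn_out)
  }

  if (isTRUE(cfg$cluster$enabled) && "intrathalamic" %in% names(results)) {
    clus <- t_stage("clustering", {
      out <- list()
      for (hemi in c("left", "right")) {
        leaves <- intersect(thalamic_nuclei_labels(hemi),
                            results$intrathalamic$nets$case$labels)
        if (length(leaves) < 4) next
        d_intra <- profile_distance(results$intrathalamic$stats$sc_diff,
                                    leaves = leaves)
        h_intra <- average_linkage(d_intra)
        k_intra <- kgs_optimal_k(h_intra, d_intra, cfg$cluster$alpha)
        entry <- list(intrathalamic_k = k_intra$k)
        dend_to_newick(h_intra,
                       file.path(out_dir,
                                 paste0("intrathalamic_", hemi, ".nwk")))
        if ("thalamocortical" %in% names(results)) {
          d_tc <- profile_distance(results$thalamocortical$stats$sc_diff,
                                   leaves = leaves)
          h_tc <- average_linkage(d_tc)
          k_tc <- kgs_optimal_k(h_tc, d_tc, cfg$cluster$alpha)
          entry$thalamocortical_k <- k_tc$k
          entry$cophenetic_r <- cophenetic_correlation(h_intra, h_tc)
          pair <- cluster_pairing_export(h_intra, h_tc, k_intra$k, k_tc$k)
          utils::write.table(
            pair, file.path(out_dir, paste0("pairing_", hemi, ".tsv")),
            sep = "\t", row.names = FALSE, quote = FALSE)
          dend_to_newick(h_tc,
                         file.path(out_dir,
                                   paste0("thalamocortical_", hemi, ".nwk")))
        }
        out[[hemi]] <- entry
      }
      out
    })
    report$clustering <- clus
  }

  report$removals <- removal_log
  report$graph_strength <- lapply(results, function(r)
    list(observed = unname(r$stats$graph$observed[1]),
         p = unname(r$stats$graph$p[1])))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
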