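# End-to-end orchestration: rarefaction -> diversity -> CLPP -> RDA ->
# network -> indicators, with seeded stages, TSV/GraphML/JSON outputs and a
# hashed MANIFEST.

env_variables <- c("DOC", "DO", "ORP", "EC", "pH", "PWT", "WT")

#' Pipeline configuration
#'
#' Collects the input paths, stage parameters and seeds of a full run. The
#' defaults are the analysis settings of the study design this package
#' implements: rarefaction to 40,205 reads (auto-lowered to the smallest
#' sample total with a warning), a 72-h CLPP snapshot, a 0.1% mean
#' relative-abundance filter, network thresholds |rho| > 0.7 and q < 0.01,
#' 1,000 Erdos-Renyi null replicates, 999 PERMANOVA and IndVal permutations,
#' and IndVal selection at indval > 0.85, q < 0.05.
#'
#' @param otu_table path to the OTU table TSV.
#' @param metadata path to the metadata TSV.
#' @param plates optional character vector of plate CSV paths, or one
#'   directory containing them; `NULL` disables the CLPP stages.
#' @param tree optional Newick tree path (enables Faith's PD).
#' @param outdir output directory.
#' @param group_col metadata column holding the group label.
#' @param group_merge optional named character vector merging group labels
#'   (e.g. `c(May = "May_August", August = "May_August")`).
#' @param depth rarefaction depth.
#' @param snapshot_h CLPP snapshot time (hours).
#' @param abundance_threshold mean relative-abundance filter for the network.
#' @param abundance_rule `"mean"`, `"all"` or `"any"` (see
#'   [filter_abundant()]).
#' @param r_threshold,q_threshold network edge thresholds.
#' @param n_perm_permanova,n_perm_indval,n_perm_rda permutation counts.
#' @param er_reps Erdos-Renyi null replicates.
#' @param indval_threshold,indval_q IndVal selection thresholds.
#' @param indval_scope `"network"` (default: test the network's OTU nodes)
#'   or `"abundant"` (test every abundance-filtered OTU).
#' @param keystone_k number of keystone nodes to report.
#' @param layout plate layout (default [eco_layout()]).
#' @param seed master integer seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(otu_table, metadata, plates = NULL, tree = NULL,
                            outdir = "clppnet_out", group_col = "group",
                            group_merge = NULL,
                            depth = 40205, snapshot_h = 72,
                            abundance_threshold = 0.001,
                            abundance_rule = "mean",
                            r_threshold = 0.7, q_threshold = 0.01,
                            n_perm_permanova = 999, n_perm_indval = 999,
                            n_perm_rda = 999, er_reps = 1000,
                            indval_threshold = 0.85, indval_q = 0.05,
                            indval_scope = c("network", "abundant"),
                            keystone_k = 10, layout = eco_layout(),
                            seed = 1) {
  indval_scope <- match.arg(indval_scope)
  if (!is.null(plates) && length(plates) == 1 && dir.exists(plates)) {
    plates <- list.files(plates, pattern = "\\.csv$", full.names = TRUE)
  }
  stopifnot(abundance_threshold > 0, abundance_threshold < 1,
            r_threshold > 0, r_threshold < 1,
            q_threshold > 0, q_threshold <= 1,
            indval_threshold > 0, indval_threshold < 1)
  structure(
    list(otu_table = otu_table, metadata = metadata, plates = plates,
         tree = tree, outdir = outdir, group_col = group_col,
         group_merge = group_merge, depth = depth, snapshot_h = snapshot_h,
         abundance_threshold = abundance_threshold,
         abundance_rule = abundance_rule,
         r_threshold = r_threshold, q_threshold = q_threshold,
         n_perm_permanova = n_perm_permanova, n_perm_indval = n_perm_indval,
         n_perm_rda = n_perm_rda, er_reps = er_reps,
         indval_threshold = indval_threshold, indval_q = indval_q,
         indval_scope = indval_scope, keystone_k = keystone_k,
         layout = layout, seed = check_seed(seed)),
    class = c("pipeline_config", "list")
  )
}

#' Validate pipeline inputs
#'
#' Checks that the referenced files exist and parse, that the OTU table and
#' metadata agree on sample ids, that plate files conform to the layout, and
#' that the tree covers the OTUs. Problems are reported as rows, not thrown.
#'
#' @param cfg a [pipeline_config()].
#' @return tibble with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows means a fully conforming bundle.
#' @export
validate_inputs <- function(cfg) {
  problems <- list()
  note <- function(level, msg) {
    problems[[length(problems) + 1]] <<- tibble(level = level, message = msg)
  }
  table <- meta <- NULL
  if (!file.exists(cfg$otu_table)) {
    note("error", paste("OTU table not found:", cfg$otu_table))
  } else {
    table <- tryCatch(read_otu_table(cfg$otu_table),
                      error = function(e) { note("error", conditionMessage(e)); NULL })
  }
  if (!file.exists(cfg$metadata)) {
    note("error", paste("Metadata not found:", cfg$metadata))
  } else {
    meta <- tryCatch(read_metadata(cfg$metadata),
                     error = function(e) { note("error", conditionMessage(e)); NULL })
  }
  if (!is.null(table) && !is.null(meta)) {
    missing_meta <- setdiff(table$sample_id, meta$sample_id)
    if (length(missing_meta)) {
      note("error", paste("Samples missing from metadata:",
                          paste(missing_meta, collapse = ", ")))
    }
    extra_meta <- setdiff(meta$sample_id, table$sample_id)
    if (length(extra_meta)) {
      note("warning", paste("Metadata samples absent from OTU table:",
                            paste(extra_meta, collapse = ", ")))
    }
    if (!cfg$group_col %in% names(meta)) {
      note("error", paste("Metadata lacks group column:", cfg$group_col))
    }
  }
  if (!is.null(cfg$tree)) {
    if (!file.exists(cfg$tree)) {
      note("error", paste("Tree not found:", cfg$tree))
    } else if (!is.null(table)) {
      tree <- tryCatch(ape::read.tree(cfg$tree),
                       error = function(e) { note("error", conditionMessage(e)); NULL })
      if (!is.null(tree)) {
        otus <- setdiff(names(table), "sample_id")
        miss <- setdiff(otus, tree$tip.label)
        if (length(miss)) {
          note("error", paste("Tree missing OTU(s):",
                              paste(head(miss, 5), collapse = ", ")))
        }
        if (length(setdiff(tree$tip.label, otus))) {
          note("warning", "Tree covers a superset of the table's OTUs.")
        }
      }
    }
  }
  if (!is.null(cfg$plates)) {
    absent <- cfg$plates[!file.exists(cfg$plates)]
    if (length(absent)) {
      note("error", paste("Plate file(s) not found:",
                          paste(absent, collapse = ", ")))
    } else {
      for (p in cfg$plates) {
        tryCatch(invisible(read_plate_series(p, layout = cfg$layout)),
                 error = function(e) note("error", sprintf("%s: %s", p,
                                                           conditionMessage(e))))
      }
    }
  }
  if (length(problems)) bind_rows(problems)
  else tibble(level = character(), message = character())
}

stage_log <- function(stage, ...) {
  inform(sprintf("[clppnet:%s] %s", stage, sprintf(...)))
}

run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "clppnet_stage_error")
  })
  stage_log(stage, "done in %.1f s", proc.time()[["elapsed"]] - t0)
  out
}

write_manifest <- function(outdir, complete) {
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "MANIFEST.tsv"))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    run_complete = complete
  )
  readr::write_tsv(manifest, file.path(outdir, "MANIFEST.tsv"))
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: input validation, rarefaction, alpha
#' diversity with Kruskal-Wallis/Dunn group tests, beta distances with PCoA
#' and PERMANOVA, CLPP metrics and PCA (when plates are configured),
#' diversity-covariate regressions, RDA of community composition and of
#' carbon utilisation against the environmental variables, the abundance
#' filter, the Spearman/FDR correlation screen, network construction with
#' node/graph topology, the Erdos-Renyi null ensemble, the degree power-law
#' check and keystone ranking, and IndVal indicator testing on the network's
#' OTU nodes. All stage tables are written under `cfg$outdir`, a
#' consolidated `report.json` summarises every stage, and `MANIFEST.tsv`
#' lists each output with its MD5 hash. Outputs carry no timestamps, so a
#' rerun with identical config and seed is byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list with the in-memory stage results and the report.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  val <- validate_inputs(cfg)
  if (any(val$level == "error")) {
    abort(paste0("Input validation failed:\n",
                 paste(val$message[val$level == "error"], collapse = "\n")))
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  on_fail <- function(e) {
    write_manifest(cfg$outdir, complete = FALSE)
    stop(e)
  }
  res <- tryCatch(run_pipeline_stages(cfg), error = on_fail)
  manifest <- write_manifest(cfg$outdir, complete = TRUE)
  invisible(c(res, list(manifest = manifest)))
}

run_pipeline_stages <- function(cfg) {
  out <- cfg$outdir
  seed <- cfg$seed
  report <- list(config = list(
    depth = cfg$depth, snapshot_h = cfg$snapshot_h,
    abundance_threshold = cfg$abundance_threshold,
    r_threshold = cfg$r_threshold, q_threshold = cfg$q_threshold,
    n_perm_permanova = cfg$n_perm_permanova,
    n_perm_indval = cfg$n_perm_indval, er_reps = cfg$er_reps,
    indval_threshold = cfg$indval_threshold, indval_q = cfg$indval_q,
    indval_scope = cfg$indval_scope, seed = seed))

  # --- inputs -------------------------------------------------------------
  table <- run_stage("read", read_otu_table(cfg$otu_table))
  meta <- read_metadata(cfg$metadata)
  meta <- meta[match(table$sample_id, meta$sample_id), ]
  groups <- as.character(meta[[cfg$group_col]])
  if (!is.null(cfg$group_merge)) {
    hit <- groups %in% names(cfg$group_merge)
    groups[hit] <- unname(cfg$group_merge[groups[hit]])
  }
  tree <- if (!is.null(cfg$tree)) ape::read.tree(cfg$tree) else NULL
  env <- meta[, intersect(env_variables, names(meta)), drop = FALSE]
  env_m <- as.matrix(env)
  rownames(env_m) <- meta$sample_id

  # --- rarefaction --------------------------------------------------------
  totals <- rowSums(otu_matrix(table))
  depth <- cfg$depth
  if (depth > min(totals)) {
    warn(sprintf("Rarefaction depth lowered from %d to the minimum sample total %d.",
                 depth, as.integer(min(totals))))
    depth <- as.integer(min(totals))
  }
  rare <- run_stage("rarefy", rarefy(table, depth, seed = seed))
  report$rarefaction <- list(depth = depth, seed = seed,
                             n_samples = nrow(rare),
                             n_otus = ncol(rare) - 1)

  # --- alpha diversity + group tests --------------------------------------
  alpha <- run_stage("alpha", alpha_diversity(rare, tree = tree))
  readr::write_tsv(alpha, file.path(out, "alpha_diversity.tsv"))
  idx_cols <- setdiff(names(alpha), "sample_id")
  alpha_groups <- groups[match(alpha$sample_id, table$sample_id)]
  alpha_tests <- purrr::map(idx_cols, function(ix) {
    by_g <- split(alpha[[ix]], alpha_groups)
    kw <- kruskal_wallis(by_g)
    dunn <- dunn_posthoc(by_g)
    tibble(index = ix, kw_h = kw$statistic, kw_p = kw$p,
           min_dunn_q = min(dunn$q))
  }) |> bind_rows()
  readr::write_tsv(alpha_tests, file.path(out, "alpha_tests.tsv"))
  report$alpha <- list(indices = idx_cols,
                       kw_p = setNames(alpha_tests$kw_p, alpha_tests$index))

  # --- beta diversity: distances, PCoA, PERMANOVA -------------------------
  beta <- run_stage("beta", {
    purrr::map(c("bray_curtis", "jaccard", "euclidean"), function(metric) {
      d <- beta_distance(rare, metric)
      write_distance_tsv(d, file.path(out, paste0("distance_", metric, ".tsv")))
      pv <- permanova(d, alpha_groups, n_perm = cfg$n_perm_permanova,
                      seed = seed + 10L)
      list(metric = metric, d = d, permanova = pv)
    })
  })
  permanova_tbl <- purrr::map(beta, function(b) {
    tidy(b$permanova) |> mutate(metric = b$metric, .before = 1)
  }) |> bind_rows()
  readr::write_tsv(permanova_tbl, file.path(out, "permanova.tsv"))
  ord <- pcoa(beta[[1]]$d)
  readr::write_tsv(ord$coordinates, file.path(out, "pcoa_coordinates.tsv"))
  readr::write_tsv(tibble(axis = seq_along(ord$eigenvalues),
                          eigenvalue = ord$eigenvalues),
                   file.path(out, "pcoa_eigenvalues.tsv"))
  report$beta <- list(
    permanova = setNames(as.list(permanova_tbl$p), permanova_tbl$metric),
    pcoa_explained = ord$explained[1:2])

  # --- CLPP ----------------------------------------------------------------
  clpp <- NULL
  if (!is.null(cfg$plates)) {
    clpp <- run_stage("clpp", {
      plates <- purrr::map(cfg$plates, read_plate_series,
                           layout = cfg$layout) |>
        bind_rows()
      plates <- plate_series(plates, layout = cfg$layout)
      resp <- blank_corrected_response(plates, time_h = cfg$snapshot_h,
                                       layout = cfg$layout)
      metrics <- clpp_metrics(resp)
      curve <- awcd_curve(plates, layout = cfg$layout)
      rsi <- rsi_matrix(resp)
      guilds <- guild_profile(resp)
      pca <- clpp_pca(rsi)
      list(resp = resp, metrics = metrics, curve = curve, rsi = rsi,
           guilds = guilds, pca = pca)
    })
    readr::write_tsv(clpp$metrics, file.path(out, "clpp_metrics.tsv"))
    readr::write_tsv(clpp$curve, file.path(out, "awcd_curve.tsv"))
    readr::write_tsv(clpp$rsi, file.path(out, "rsi_matrix.tsv"))
    readr::write_tsv(clpp$guilds, file.path(out, "guild_profile.tsv"))
    readr::write_tsv(clpp$pca$scores, file.path(out, "clpp_pca_scores.tsv"))
    readr::write_tsv(clpp$pca$loadings,
                     file.path(out, "clpp_pca_loadings.tsv"))
    clpp_groups <- groups[match(clpp$metrics$sample_id, table$sample_id)]
    kw_awcd <- kruskal_wallis(split(clpp$metrics$awcd, clpp_groups))
    report$clpp <- list(
      snapshot_h = clpp$metrics$time_h[1],
      mean_awcd = mean(clpp$metrics$awcd),
      mean_mcintosh_u = mean(clpp$metrics$mcintosh_u),
      mean_shannon_h = mean(clpp$metrics$shannon_h),
      awcd_kw_p = kw_awcd$p,
      pca_explained = clpp$pca$explained[1:2])
  }

  # --- regressions ---------------------------------------------------------
  regr <- NULL
  if (ncol(env) > 0) {
    regr <- run_stage("regressions", {
      rows <- list()
      if ("WT" %in% names(env)) {
        wt <- env$WT[match(alpha$sample_id, meta$sample_id)]
        for (ix in intersect(c("faith_pd", "chao1", "shannon"), idx_cols)) {
          rows[[length(rows) + 1]] <-
            regress_on_covariate(alpha[[ix]], wt) |>
            mutate(response = ix, covariate = "WT", .before = 1)
        }
      }
      if (!is.null(clpp) && "PWT" %in% names(env)) {
        pwt <- env$PWT[match(clpp$metrics$sample_id, meta$sample_id)]
        rows[[length(rows) + 1]] <-
          regress_on_covariate(clpp$metrics$mcintosh_u, pwt) |>
          mutate(response = "mcintosh_u", covariate = "PWT", .before = 1)
      }
      bind_rows(rows)
    })
    if (nrow(regr)) readr::write_tsv(regr, file.path(out, "regressions.tsv"))
    report$regressions <- purrr::pmap(
      regr[, c("response", "covariate", "slope", "p")], list)
  }

  # --- abundance filter ----------------------------------------------------
  abundant <- run_stage("filter",
                        filter_abundant(rare, cfg$abundance_threshold,
                                        rule = cfg$abundance_rule))
  rel <- relative_abundance(abundant)
  report$filter <- list(n_abundant = ncol(abundant) - 1,
                        threshold = cfg$abundance_threshold,
                        rule = cfg$abundance_rule)

  # --- RDA -----------------------------------------------------------------
  if (ncol(env) >= 1) {
    env_rel <- env_m[match(rel$sample_id, rownames(env_m)), , drop = FALSE]
    rda_otu <- run_stage("rda", rda(rel, env_rel, n_perm = cfg$n_perm_rda,
                                    seed = seed + 20L))
    readr::write_tsv(rda_otu$site_scores, file.path(out, "rda_otu_sites.tsv"))
    readr::write_tsv(rda_otu$predictor_scores,
                     file.path(out, "rda_otu_predictors.tsv"))
    jsonlite::write_json(
      list(total_constrained_fraction = rda_otu$total_constrained_fraction,
           axis_fractions = rda_otu$constrained_fractions,
           p_overall = rda_otu$p_overall,
           p_per_predictor = as.list(rda_otu$p_per_predictor)),
      file.path(out, "rda_otu_summary.json"), auto_unbox = TRUE, digits = NA)
    report$rda_otu <- list(
      total_constrained_fraction = rda_otu$total_constrained_fraction,
      p_overall = rda_otu$p_overall,
      p_per_predictor = as.list(rda_otu$p_per_predictor))
    if (!is.null(clpp)) {
      env_clpp <- env_m[match(clpp$rsi$sample_id, rownames(env_m)), ,
                        drop = FALSE]
      rda_clpp <- rda(clpp$rsi, env_clpp, n_perm = cfg$n_perm_rda,
                      seed = seed + 21L)
      jsonlite::write_json(
        list(total_constrained_fraction = rda_clpp$total_constrained_fraction,
             axis_fractions = rda_clpp$constrained_fractions,
             p_overall = rda_clpp$p_overall,
             p_per_predictor = as.list(rda_clpp$p_per_predictor)),
        file.path(out, "rda_clpp_summary.json"), auto_unbox = TRUE,
        digits = NA)
      report$rda_clpp <- list(
        total_constrained_fraction = rda_clpp$total_constrained_fraction,
        p_overall = rda_clpp$p_overall)
    }
  }

  # --- network -------------------------------------------------------------
  net <- run_stage("network", {
    screen <- correlation_screen(rel, env = if (ncol(env)) env_m else NULL)
    g <- build_network(screen, r_threshold = cfg$r_threshold,
                       q_threshold = cfg$q_threshold)
    ntopo <- node_topology(g)
    gtopo <- graph_topology(g)
    ntopo$module <- unname(gtopo$module_of[ntopo$node])
    nulls <- er_null_ensemble(g, n_reps = cfg$er_reps, seed = seed + 30L)
    pl <- tryCatch(degree_powerlaw_check(g), error = function(e) NULL)
    ks <- keystones(ntopo, k = cfg$keystone_k)
    list(screen = screen, g = g, ntopo = ntopo, gtopo = gtopo,
         nulls = nulls, powerlaw = pl, keystones = ks)
  })
  edges <- igraph::as_data_frame(net$g, what = "edges") |>
    rename(source = "from", target = "to") |> as_tibble()
  readr::write_tsv(edges, file.path(out, "network_edges.tsv"))
  readr::write_tsv(net$ntopo, file.path(out, "network_nodes.tsv"))
  readr::write_tsv(net$keystones, file.path(out, "keystones.tsv"))
  readr::write_tsv(tidy(net$nulls), file.path(out, "null_ensemble.tsv"))
  jsonlite::write_json(
    list(n_reps = net$nulls$n_reps, seed = net$nulls$seed,
         summary = tidy(net$nulls)),
    file.path(out, "null_ensemble.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(net$powerlaw)) {
    readr::write_tsv(net$powerlaw, file.path(out, "degree_powerlaw.tsv"))
  }
  report$network <- c(
    as.list(glance(net$gtopo)),
    list(n_isolated = igraph::graph_attr(net$g, "n_isolated"),
         keystone_nodes = net$keystones$node))

  # --- indicators ----------------------------------------------------------
  ind_table <- if (cfg$indval_scope == "network") {
    otu_nodes <- net$ntopo$node[net$ntopo$kind == "otu"]
    abundant[, c("sample_id", intersect(names(abundant), otu_nodes))]
  } else abundant
  ind <- run_stage("indicators", {
    indval_test(ind_table, groups[match(ind_table$sample_id, table$sample_id)],
                n_perm = cfg$n_perm_indval, seed = seed + 40L,
                indval_threshold = cfg$indval_threshold,
                q_threshold = cfg$indval_q)
  })
  readr::write_tsv(as_tibble(ind), file.path(out, "indicators.tsv"))
  report$indicators <- list(
    scope = cfg$indval_scope,
    n_tested = nrow(ind),
    n_selected = sum(ind$selected),
    selected = ind$otu_id[ind$selected])

  # GraphML export with modules and indicator flags as node attributes
  g_out <- net$g
  g_out <- igraph::set_vertex_attr(
    g_out, "module", value = unname(net$gtopo$module_of[igraph::V(g_out)$name]))
  sel <- igraph::V(g_out)$name %in% ind$otu_id[ind$selected]
  g_out <- igraph::set_vertex_attr(g_out, "indicator", value = sel)
  best <- ind$best_group[match(igraph::V(g_out)$name, ind$otu_id)]
  g_out <- igraph::set_vertex_attr(
    g_out, "indicator_group", value = ifelse(sel, best, ""))
  igraph::write_graph(g_out, file.path(out, "network.graphml"),
                      format = "graphml")

  report$stages_completed <- c(
    "rarefy", "alpha", "beta", if (!is.null(clpp)) "clpp",
    if (!is.null(regr)) "regressions", "filter",
    if (ncol(env) >= 1) "rda", "network", "indicators")
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(report = report, alpha = alpha, beta = beta, clpp = clpp,
                 network = net, indicators = ind, rarefied = rare,
                 groups = groups))
}
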