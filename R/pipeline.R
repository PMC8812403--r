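# End-to-end pipeline ----------------------------------------------------
#
# One config drives: simulate -> quantify -> stats -> networks -> clusters
# -> scoring -> closeness -> miRNA.  Every stage writes plain-text
# artifacts into the output directory; the manifest records files,
# checksums and the seed so a rerun with the same config reproduces
# identical outputs.

#' Default pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @return Nested configuration list; override entries before passing to
#'   [run_pipeline()].  Thresholds default to the analysis conventions:
#'   network p < 0.05 (loose) and |r| > 0.73, p < 0.01 (strict), cut
#'   heights 1.0 and 2.0, scoring on at most 4 strongest pairs, miRNA
#'   degree filter 3.
#' @export
pipeline_config <- function(outdir = tempfile("takcoex_run_"), seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(enabled = TRUE),
    input = list(cq = NULL, samples = NULL),
    quantify = list(calibrator_group = "HC"),
    network = list(method = "pearson", p_loose = 0.05,
                   p_strict = 0.01, r_strict = 0.73),
    cluster = list(cut_height = 1.0, cut_height_sub = 2.0),
    score = list(fit_group = "treated-inactive",
                 apply_groups = c("treated-inactive", "treated-active"),
                 max_pairs = 4),
    closeness = list(tlr_set = default_tlr_set()),
    mirna = list(target_map = NULL, min_degree = 3)
  )
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  base <- pipeline_config()
  modifyList(base, config, keep.null = TRUE)
}

.manifest_add <- function(manifest, stage, files, extra = NULL) {
  files <- files[file.exists(files)]
  manifest$stages[[stage]] <- c(list(
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files)))),
    extra)
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes all configured stages in dependency order on either a
#' synthetic cohort (default) or Cq/sample tables read from
#' `config$input`.  Failure of any stage aborts with a stage-tagged
#' error.
#'
#' @param config A [pipeline_config()] list, or a path to a YAML/JSON
#'   file with overrides.
#' @return The run manifest (invisibly written as `manifest.json` in the
#'   output directory): seed, config, per-stage output files with MD5
#'   checksums, and key results (topology table, reference pair, ROC).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- .read_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("takcoex")),
                   seed = cfg$seed, config = cfg, stages = list())
  stage <- function(name, body) {
    tryCatch(body(), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  # -- simulate / load ---------------------------------------------------
  dat <- stage("simulate", function() {
    if (isTRUE(cfg$simulate$enabled)) {
      cc <- cohort_config(seed = cfg$seed)
      coh <- generate_cohort(cc)
      samples <- generate_clinical(cc, coh$samples)
      list(cq = coh$cq, samples = samples, config = cc)
    } else {
      if (is.null(cfg$input$cq) || is.null(cfg$input$samples))
        stop("simulation disabled and no input files given")
      list(cq = read_cq_matrix(cfg$input$cq),
           samples = read.csv(cfg$input$samples, stringsAsFactors = FALSE),
           config = NULL)
    }
  })
  f_cq <- file.path(cfg$outdir, "cq_matrix.tsv")
  f_samples <- file.path(cfg$outdir, "samples.csv")
  write_cq_matrix(dat$cq, f_cq)
  write.csv(dat$samples, f_samples, row.names = FALSE)
  manifest <- .manifest_add(manifest, "simulate", c(f_cq, f_samples))

  ref_candidates <- intersect(default_reference_spec()$gene,
                              rownames(dat$cq))
  targets <- setdiff(rownames(dat$cq), ref_candidates)
  groups <- dat$samples$group[match(colnames(dat$cq), dat$samples$sample_id)]

  # -- quantify ----------------------------------------------------------
  q <- stage("quantify", function() {
    rep <- stability_report(dat$cq[ref_candidates, , drop = FALSE], groups)
    pair <- select_reference_pair(rep)
    cal <- dat$samples$sample_id[groups == cfg$quantify$calibrator_group]
    expr <- relative_expression(dat$cq, targets, pair, cal)
    list(report = rep, pair = pair, expr = expr)
  })
  f_stab <- file.path(cfg$outdir, "stability_report.csv")
  f_expr <- file.path(cfg$outdir, "expression.tsv")
  write.csv(as.data.frame(q$report), f_stab, row.names = FALSE)
  write_cq_matrix(unclass(q$expr), f_expr)
  manifest <- .manifest_add(manifest, "quantify", c(f_stab, f_expr),
                            list(reference_pair = q$pair))

  # -- stats -------------------------------------------------------------
  st <- stage("stats", function() {
    de <- differential_expression(q$expr, dat$samples,
                                  c("treated-inactive", "treated-active"))
    covs <- intersect(c("age", "duration", "ESR", "hsCRP", "IL6", "TNFa",
                        "prednisone"), names(dat$samples))
    demo <- NULL
    if (length(covs)) {
      ia <- dat$samples$group == "treated-inactive"
      ac <- dat$samples$group == "treated-active"
      demo <- do.call(rbind, lapply(covs, function(v) {
        t <- mann_whitney(dat$samples[[v]][ia], dat$samples[[v]][ac])
        data.frame(variable = v, U = t$statistic, p_value = t$p_value,
                   stringsAsFactors = FALSE)
      }))
    }
    list(de = de, demo = demo)
  })
  f_de <- file.path(cfg$outdir, "differential_expression.csv")
  write.csv(st$de, f_de, row.names = FALSE)
  files <- f_de
  if (!is.null(st$demo)) {
    f_demo <- file.path(cfg$outdir, "demographics.csv")
    write.csv(st$demo, f_demo, row.names = FALSE)
    files <- c(files, f_demo)
  }
  manifest <- .manifest_add(manifest, "stats", files)

  # -- networks ----------------------------------------------------------
  conds <- unique(dat$samples$group)
  nets <- stage("network", function() {
    lapply(setNames(conds, conds), function(cd) {
      ids <- dat$samples$sample_id[dat$samples$group == cd]
      corr <- pairwise_correlation(q$expr, method = cfg$network$method,
                                   condition_samples = ids)
      list(corr = corr,
           loose = build_network(corr, p_max = cfg$network$p_loose,
                                 condition = cd),
           strict = build_network(corr, p_max = cfg$network$p_strict,
                                  r_min = cfg$network$r_strict,
                                  condition = cd))
    })
  })
  topo <- do.call(rbind, lapply(conds, function(cd) {
    tm <- topology(nets[[cd]]$loose)
    data.frame(condition = cd, nodes = tm$nodes, edges = tm$edges,
               average_neighbors = tm$average_neighbors,
               diameter = tm$diameter,
               clustering_coefficient = tm$clustering_coefficient,
               characteristic_path_length = tm$characteristic_path_length,
               stringsAsFactors = FALSE)
  }))
  f_topo <- file.path(cfg$outdir, "topology.tsv")
  utils::write.table(topo, f_topo, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  net_files <- f_topo
  for (cd in conds) {
    f_sif <- file.path(cfg$outdir, sprintf("network_%s.sif", cd))
    write_sif(nets[[cd]]$loose, f_sif)
    f_json <- file.path(cfg$outdir, sprintf("network_%s.json", cd))
    write_network_json(nets[[cd]]$loose, f_json)
    net_files <- c(net_files, f_sif, paste0(f_sif, ".attrs.tsv"), f_json)
  }
  manifest <- .manifest_add(manifest, "network", net_files,
                            list(topology = topo))

  # -- clustering --------------------------------------------------------
  clus <- stage("cluster", function() {
    lapply(setNames(conds, conds), function(cd) {
      ids <- dat$samples$sample_id[dat$samples$group == cd]
      d <- correlation_distance(q$expr[, ids, drop = FALSE],
                                method = cfg$network$method)
      hc <- hierarchical_cluster(d)
      list(hc = hc,
           modules = cut_tree(hc, cfg$cluster$cut_height),
           submodules = cut_tree(hc, cfg$cluster$cut_height_sub))
    })
  })
  clus_files <- character(0)
  for (cd in conds) {
    f_asg <- file.path(cfg$outdir, sprintf("clusters_%s.tsv", cd))
    asg <- clus[[cd]]$modules$assignment
    utils::write.table(data.frame(gene = names(asg), cluster = asg),
                       f_asg, sep = "\t", quote = FALSE, row.names = FALSE)
    f_nwk <- file.path(cfg$outdir, sprintf("dendrogram_%s.nwk", cd))
    write_newick(clus[[cd]]$hc, f_nwk)
    clus_files <- c(clus_files, f_asg, f_nwk)
  }
  manifest <- .manifest_add(manifest, "cluster", clus_files)

  # -- activity score ----------------------------------------------------
  sc <- stage("score", function() {
    fit_grp <- cfg$score$fit_group
    if (!fit_grp %in% conds) stop("fit group absent: ", fit_grp)
    pairs <- select_pairs(nets[[fit_grp]]$corr,
                          r_min = cfg$network$r_strict,
                          alpha = cfg$network$p_strict)
    if (!nrow(pairs)) return(NULL)
    pairs <- head(pairs, cfg$score$max_pairs)
    fit_ids <- dat$samples$sample_id[dat$samples$group == fit_grp]
    apply_ids <- dat$samples$sample_id[dat$samples$group %in%
                                         cfg$score$apply_groups]
    labels <- dat$samples$activity[match(apply_ids, dat$samples$sample_id)]
    models <- lapply(seq_len(nrow(pairs)), function(i)
      fit_pair_regression(q$expr, pairs$gene_a[i], pairs$gene_b[i], fit_ids))
    thresholds <- vapply(models, function(m) {
      mv <- suppressWarnings(m_value(m, q$expr, apply_ids)$M)
      youden_threshold(mv, labels, positive = "active")$threshold
    }, numeric(1))
    card <- combined_score(models, thresholds, q$expr, apply_ids)
    yt <- youden_threshold(card$total, labels, positive = "active",
                           direction = "<")
    card$classification <- ifelse(card$total >= yt$threshold,
                                  "inactive", "active")
    list(pairs = pairs, models = models, thresholds = thresholds,
         card = card, total_threshold = yt$threshold, roc = yt$roc)
  })
  if (!is.null(sc)) {
    f_card <- file.path(cfg$outdir, "score_card.csv")
    write.csv(as.data.frame(sc$card), f_card, row.names = FALSE)
    f_models <- file.path(cfg$outdir, "score_models.json")
    jsonlite::write_json(list(
      pairs = sc$pairs,
      models = lapply(sc$models, function(m)
        m[c("x_gene", "y_gene", "slope", "intercept", "r", "p", "n")]),
      pair_thresholds = sc$thresholds,
      total_threshold = sc$total_threshold,
      roc = unclass(sc$roc)), f_models, auto_unbox = TRUE, digits = NA)
    manifest <- .manifest_add(manifest, "score", c(f_card, f_models),
                              list(roc = unclass(sc$roc)))
  }

  # -- closeness ---------------------------------------------------------
  cl <- stage("closeness", function() {
    fit_grp <- cfg$score$fit_group
    closeness_table(nets[[fit_grp]]$loose, clus[[fit_grp]]$modules,
                    tlr_set = cfg$closeness$tlr_set)
  })
  f_close <- file.path(cfg$outdir, "closeness.csv")
  write.csv(cl, f_close, row.names = FALSE)
  manifest <- .manifest_add(manifest, "closeness", f_close,
                            list(closeness = cl))

  # -- miRNA -------------------------------------------------------------
  if (!is.null(cfg$mirna$target_map)) {
    mi <- stage("mirna", function() {
      map <- if (inherits(cfg$mirna$target_map, "mirna_target_map"))
        cfg$mirna$target_map else read_target_map(cfg$mirna$target_map)
      map <- pool_families(filter_multi_target(map))
      list(ranking = rank_by_target_count(map),
           network = build_mirna_network(map,
                                         min_degree = cfg$mirna$min_degree))
    })
    f_rank <- file.path(cfg$outdir, "mirna_ranking.tsv")
    utils::write.table(mi$ranking, f_rank, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f_edges <- file.path(cfg$outdir, "mirna_network.tsv")
    utils::write.table(mi$network$edges, f_edges, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- .manifest_add(manifest, "mirna", c(f_rank, f_edges))
  }

  f_manifest <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(manifest)
}

#' Human-readable summary of a pipeline run
#'
#' Prints the stage inventory, the reference pair, a per-condition
#' topology table (the six standard network metrics), the closeness table
#' head, and the combined-score ROC, at the field's usual precision
#' (r to 3 decimals, p to 2-4 significant digits).  Sections whose stage
#' did not run are omitted.
#'
#' @param manifest A [run_pipeline()] manifest (or path to
#'   `manifest.json`).
#' @return The formatted report lines, invisibly; printed as a side
#'   effect.
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  out <- c(sprintf("takcoex pipeline report (seed %d)", manifest$seed),
           sprintf("stages run: %s",
                   paste(names(manifest$stages), collapse = ", ")))
  if (!is.null(manifest$stages$quantify$reference_pair))
    out <- c(out, sprintf("reference genes: %s",
                          paste(unlist(manifest$stages$quantify$reference_pair),
                                collapse = " + ")))
  topo <- manifest$stages$network$topology
  if (!is.null(topo)) {
    topo <- as.data.frame(topo)
    out <- c(out, "", "network topology (p < 0.05 networks):",
             sprintf("  %-20s %5s %5s %9s %8s %10s %10s", "condition",
                     "nodes", "edges", "avg.neigh", "diameter",
                     "clust.coef", "char.path"))
    for (i in seq_len(nrow(topo)))
      out <- c(out, sprintf("  %-20s %5d %5d %9.3f %8g %10.3f %10.3f",
                            topo$condition[i], topo$nodes[i], topo$edges[i],
                            topo$average_neighbors[i], topo$diameter[i],
                            topo$clustering_coefficient[i],
                            topo$characteristic_path_length[i]))
  }
  cl <- manifest$stages$closeness$closeness
  if (!is.null(cl)) {
    cl <- utils::head(as.data.frame(cl), 7)
    out <- c(out, "", "TLR-closeness (top genes):",
             sprintf("  %-8s %9s %9s %9s %6s", "gene", "coexpr.", "common",
                     "cluster", "total"))
    for (i in seq_len(nrow(cl)))
      out <- c(out, sprintf("  %-8s %9d %9d %9d %6d", cl$gene[i],
                            cl$coexpressed_tlrs[i], cl$common_neighbors[i],
                            cl$tlrs_in_cluster[i], cl$total[i]))
  }
  roc <- manifest$stages$score$roc
  if (!is.null(roc))
    out <- c(out, "", sprintf(
      "combined M-value score: AUC %.3f, sens %.1f%%, spec %.1f%%",
      roc$auc, 100 * roc$sensitivity, 100 * roc$specificity))
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
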