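# End-to-end orchestration: simulate (or load) inputs, run every analysis
# stage, write per-stage TSV outputs and a run manifest.

pipeline_defaults <- function() {
  list(seed = 1L,
       stages = c("simulate", "network", "traits", "hubs", "enrich",
                  "survival", "ptm", "cluster", "classify"),
       beta = 10, n_top_genes = 5000L, min_module_size = 50L,
       merge_cut_height = 0.25, deep_split = 2L,
       r_threshold = 0.3, p_threshold = 0.1,
       n_hubs = 10L, weight_threshold = 0.2,
       top_n_prognostic = 500L, alpha = 0.05,
       expression_file = NULL, metadata_file = NULL, cohort_file = NULL,
       ptm_file = NULL, gmt_file = NULL, ortholog_file = NULL,
       fcm_c = "auto", fcm_m = "auto",
       sim = list())
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: input simulation (or loading from the
#' configured files), co-expression network fit, module-trait correlation,
#' hub selection and trait subnetworks, gene-set enrichment, the survival
#' screen with signature scoring, PTM quantification and statistics, fuzzy
#' clustering, and phenotype classification. Each stage writes TSV outputs
#' into `out_dir`; a fully-resolved copy of the configuration and a manifest
#' (package version, seed, parameter hash) are written alongside. Reruns with
#' the same config and inputs are byte-identical.
#'
#' @param config named list of overrides, or a YAML file path; unknown keys
#'   are rejected. See `melprog:::pipeline_defaults()` for the full set.
#' @param out_dir output directory (created; must be empty or absent unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the key in-memory results per stage.
#' @export
run_pipeline <- function(config = list(), out_dir, overwrite = FALSE) {
  if (is.character(config)) {
    stop_if(!file.exists(config), "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  stop_if(length(unknown) > 0,
          "unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (f in c("expression_file", "metadata_file", "cohort_file", "ptm_file",
              "gmt_file", "ortholog_file"))
    stop_if(!is.null(cfg[[f]]) && !file.exists(cfg[[f]]),
            "input file not found: ", cfg[[f]])
  stop_if(dir.exists(out_dir) && !overwrite &&
            length(list.files(out_dir)) > 0,
          "output directory not empty: ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage ", name, " failed: ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  stage("simulate", function() {
    if (is.null(cfg$expression_file)) {
      sim <- simulate_expression(scfg)
      res$expr <<- sim$expr; res$meta <<- sim$meta
      write_expression_tsv(sim$expr, file.path(out_dir, "expression.tsv"))
      write_sample_metadata(sim$meta, file.path(out_dir, "samples.tsv"))
      write_ground_truth(sim$truth, file.path(out_dir, "truth_expression"))
    } else {
      res$expr <<- read_expression_tsv(cfg$expression_file)
      res$meta <<- read_sample_metadata(cfg$metadata_file)
    }
    if (is.null(cfg$cohort_file)) {
      sim <- simulate_cohort(scfg)
      res$cohort <<- sim$cohort
      write_cohort_tsv(sim$cohort, file.path(out_dir, "cohort.tsv"))
      write_ground_truth(sim$truth, file.path(out_dir, "truth_cohort"))
    } else res$cohort <<- read_cohort_tsv(cfg$cohort_file)
    if (is.null(cfg$ptm_file)) {
      sim <- simulate_ptm_table(scfg)
      res$ptm_raw <<- sim$ptm; res$ptm_meta <<- sim$meta
      write_ptm_csv(sim$ptm, file.path(out_dir, "ptm_areas.csv"))
      write_ground_truth(sim$truth, file.path(out_dir, "truth_ptm"))
    } else {
      res$ptm_raw <<- parse_ptm_table(cfg$ptm_file)
      res$ptm_meta <<- res$meta
    }
  })

  stage("network", function() {
    fit <- coexpress(res$expr, beta = cfg$beta, n_top_genes = cfg$n_top_genes,
                     min_module_size = cfg$min_module_size,
                     merge_cut_height = cfg$merge_cut_height,
                     deep_split = cfg$deep_split)
    res$fit <<- fit
    utils::write.table(
      data.frame(gene = names(fit$modules), module = unname(fit$modules)),
      file.path(out_dir, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(module = rownames(fit$eigengenes),
                 apply(fit$eigengenes, 2, fmt_num), check.names = FALSE),
      file.path(out_dir, "eigengenes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    conn <- fit$connectivity
    conn$k_within <- fmt_num(conn$k_within); conn$k_total <- fmt_num(conn$k_total)
    utils::write.table(conn, file.path(out_dir, "connectivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("traits", function() {
    tr <- encode_traits(res$meta)
    mt <- module_trait_correlation(res$fit$eigengenes, tr,
                                   r_threshold = cfg$r_threshold,
                                   p_threshold = cfg$p_threshold)
    res$module_trait <<- mt
    out <- as.data.frame(mt)
    out$r <- fmt_num(out$r); out$p <- fmt_num(out$p)
    utils::write.table(out, file.path(out_dir, "module_trait.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("hubs", function() {
    hubs <- select_hubs(res$fit$connectivity, n_hubs = cfg$n_hubs)
    res$hubs <<- hubs
    hub_df <- do.call(rbind, lapply(names(hubs), function(m)
      data.frame(module = m, rank = seq_len(nrow(hubs[[m]])),
                 hubs[[m]], stringsAsFactors = FALSE)))
    hub_df$k_within <- fmt_num(hub_df$k_within)
    utils::write.table(hub_df, file.path(out_dir, "hubs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mt <- res$module_trait
    if (!is.null(mt)) {
      for (trait in unique(mt$trait)) {
        mods <- mt$module[mt$trait == trait & mt$significant &
                            mt$sign == "+" & mt$module != "grey"]
        mods <- intersect(mods, names(hubs))
        if (length(mods) < 1) next
        g <- suppressWarnings(
          build_hub_subnetwork(res$fit$expr, hubs, mods, beta = cfg$beta,
                               weight_threshold = cfg$weight_threshold))
        if (igraph::ecount(g) > 0)
          write_subnetwork(g, file.path(out_dir,
                                        paste0("subnetwork_", trait, ".tsv")),
                           file.path(out_dir,
                                     paste0("subnetwork_", trait, ".graphml")))
      }
    }
  })

  stage("survival", function() {
    genes <- grep("^gene[0-9]+$", names(res$cohort), value = TRUE)
    scr <- gene_wise_survival_screen(res$cohort, genes)
    res$screen <<- scr
    out <- scr
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
    utils::write.table(out, file.path(out_dir, "survival_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$prognostic <<- rank_prognostic_genes(scr,
                                             min(cfg$top_n_prognostic,
                                                 nrow(scr)))
    writeLines(res$prognostic, file.path(out_dir, "prognostic_genes.txt"))
  })

  stage("enrich", function() {
    sets <- if (!is.null(cfg$gmt_file)) read_gmt(cfg$gmt_file) else NULL
    if (is.null(sets)) return(invisible(NULL))
    map <- if (!is.null(cfg$ortholog_file)) read_ortholog_map(cfg$ortholog_file)
    enr <- hypergeometric_enrichment(res$fit$modules, sets, map = map,
                                     alpha = cfg$alpha)
    res$enrichment <<- enr
    enr$p <- fmt_num(enr$p); enr$p_adj <- fmt_num(enr$p_adj)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  stage("ptm", function() {
    ptm <- if (inherits(res$ptm_raw, "ptm_table")) res$ptm_raw else
      parse_ptm_table(res$ptm_raw)
    ab <- relative_abundance(ptm)
    res$abundance <<- ab
    groups <- res$ptm_meta$cell_line[match(ab$samples, res$ptm_meta$sample)]
    res$ptm_groups <<- groups
    stats_ <- anova_tukey(ab$ratios, groups, alpha = cfg$alpha)
    res$ptm_stats <<- stats_
    gl <- global_mark_levels(ab)
    utils::write.table(
      data.frame(mark_class = rownames(gl), apply(gl, 2, fmt_num),
                 check.names = FALSE),
      file.path(out_dir, "global_marks.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    out <- as.data.frame(stats_)
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
    utils::write.table(out, file.path(out_dir, "ptm_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  stage("cluster", function() {
    fit <- fuzzy_cmeans(res$abundance$ratios, c = cfg$fcm_c, m = cfg$fcm_m,
                        seed = cfg$seed)
    res$fcm <<- fit
    u <- fit$membership
    utils::write.table(
      data.frame(form = rownames(res$abundance$ratios),
                 cluster = fit$cluster,
                 apply(u, 2, fmt_num), check.names = FALSE),
      file.path(out_dir, "fcm_membership.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  })

  stage("classify", function() {
    pat <- significance_pattern(res$abundance$ratios, res$ptm_groups,
                                alpha = cfg$alpha, stats = res$ptm_stats)
    assign <- classify_ptm(pat)
    res$assignments <<- assign
    utils::write.table(assign, file.path(out_dir, "ptm_phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$fcm)) {
      cl <- suppressMessages(
        classify_cluster(res$fcm, assign, res$ptm_groups))
      res$cluster_labels <<- cl
      utils::write.table(cl, file.path(out_dir, "cluster_phenotypes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  resolved <- cfg
  resolved$sim <- scfg[setdiff(names(scfg), "module_specs")]
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
  manifest <- list(package = "melprog",
                   version = as.character(utils::packageVersion("melprog")),
                   seed = cfg$seed,
                   stages = cfg$stages,
                   parameter_hash = param_hash(cfg))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}

# order-independent hash of the resolved parameters (djb2 over the
# deparsed config; no external digest dependency)
param_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
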