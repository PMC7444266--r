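# Synthetic-data generators with planted ground truth.
#
# The generators emulate the study design of a four-line melanoma-progression
# panel profiled in triplicate: an expression matrix with planted co-expression
# modules whose eigen-profiles follow phenotype encodings, a survival cohort
# with planted per-gene log-hazards, and a histone-PTM peptide-area table whose
# modified forms follow progression/EMT/metastasis archetype profiles.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators in one validated
#' list. All downstream draws flow from `seed`.
#'
#' @param seed integer seed; identical configs and seeds give byte-identical
#'   outputs.
#' @param module_specs data.frame with columns `size` (genes per planted
#'   module), `trait_pattern` (one of `"progression"`, `"emt"`, `"metastasis"`,
#'   `"tumor"`, `"null"`), `sign` (+1/-1 orientation of the pattern, optional),
#'   `loading_mean` and `noise_sd`. Defaults plant six
#'   modules of 300...50 genes with unit mean loading and residual SD 0.5 on
#'   the log-expression scale.
#' @param n_background genes with no planted structure (pure noise).
#' @param n_replicates replicates per cell line (panel design is fixed at the
#'   four lines `cell_lines()`).
#' @param profile_noise_sd SD of per-sample jitter added to each planted
#'   module eigen-profile, on top of the line-level pattern. Keeps modules
#'   sharing correlated patterns distinguishable, as replicate-level
#'   variability does in real panels.
#' @param loading_sdlog log-scale SD of per-gene loadings (lognormal around
#'   `loading_mean`); spreads intramodular connectivity so hub genes exist.
#' @param cohort_size patients in the simulated survival cohort.
#' @param n_cohort_genes genes carried in the cohort table.
#' @param n_prognostic how many of those genes get a non-zero planted
#'   log-hazard.
#' @param planted_log_hr planted log hazard ratio per SD of expression for
#'   prognostic genes.
#' @param censoring_rate target fraction of censored records in `[0, 1)`.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param survival_shape Weibull shape; 1 (default) gives exponential times.
#' @param n_peptides peptide backbones in the PTM table.
#' @param n_forms total modified + unmodified peptide forms.
#' @param ptm_noise_sdlog lognormal SD of replicate noise on peptide areas.
#' @param archetype_mix non-negative weights over the 8 PTM archetypes
#'   (see [ptm_archetypes()]); normalised to sum to 1.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       module_specs = data.frame(
                         size = c(300L, 250L, 200L, 150L, 100L, 50L),
                         trait_pattern = c("progression", "emt", "metastasis",
                                           "null", "null", "null"),
                         sign = c(-1, 1, 1, 1, 1, 1),
                         loading_mean = 1,
                         noise_sd = 0.5),
                       n_background = 450L,
                       n_replicates = 3L,
                       profile_noise_sd = 0.6,
                       loading_sdlog = 0.5,
                       cohort_size = 500L,
                       n_cohort_genes = 100L,
                       n_prognostic = 10L,
                       planted_log_hr = 0.4,
                       censoring_rate = 0.3,
                       baseline_hazard = 0.01,
                       survival_shape = 1,
                       n_peptides = 60L,
                       n_forms = 245L,
                       ptm_noise_sdlog = 0.10,
                       archetype_mix = rep(1 / 8, 8)) {
  stop_if(length(seed) != 1L || is.na(seed), "'seed' must be a single integer")
  req <- c("size", "trait_pattern", "loading_mean", "noise_sd")
  if (is.null(module_specs$sign)) module_specs$sign <- 1
  stop_if(!is.data.frame(module_specs) || !all(req %in% names(module_specs)),
          "'module_specs' needs columns ", paste(req, collapse = ", "))
  ok <- c("progression", "emt", "metastasis", "tumor", "null")
  bad <- setdiff(module_specs$trait_pattern, ok)
  stop_if(length(bad) > 0, "unknown trait_pattern: ", paste(bad, collapse = ", "))
  stop_if(any(module_specs$size <= 0), "module sizes must be positive")
  stop_if(!all(module_specs$sign %in% c(-1, 1)), "'sign' must be -1 or 1")
  stop_if(any(module_specs$noise_sd < 0), "noise_sd must be non-negative")
  stop_if(n_background < 0, "'n_background' must be >= 0")
  stop_if(n_replicates < 1, "'n_replicates' must be >= 1")
  stop_if(cohort_size < 0, "negative cohort_size")
  stop_if(censoring_rate < 0 || censoring_rate >= 1,
          "'censoring_rate' must be in [0, 1)")
  stop_if(n_prognostic > n_cohort_genes,
          "'n_prognostic' cannot exceed 'n_cohort_genes'")
  stop_if(n_forms < n_peptides, "'n_forms' must be >= 'n_peptides'")
  stop_if(length(archetype_mix) != 8 || any(archetype_mix < 0) ||
            sum(archetype_mix) <= 0, "'archetype_mix' must be 8 non-negative weights")
  cfg <- list(seed = as.integer(seed), module_specs = module_specs,
              n_background = as.integer(n_background),
              n_replicates = as.integer(n_replicates),
              profile_noise_sd = profile_noise_sd,
              loading_sdlog = loading_sdlog,
              cohort_size = as.integer(cohort_size),
              n_cohort_genes = as.integer(n_cohort_genes),
              n_prognostic = as.integer(n_prognostic),
              planted_log_hr = planted_log_hr,
              censoring_rate = censoring_rate,
              baseline_hazard = baseline_hazard,
              survival_shape = survival_shape,
              n_peptides = as.integer(n_peptides),
              n_forms = as.integer(n_forms),
              ptm_noise_sdlog = ptm_noise_sdlog,
              archetype_mix = archetype_mix / sum(archetype_mix))
  cfg$n_genes <- sum(module_specs$size) + cfg$n_background
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config (seed ", x$seed, ")\n", sep = "")
  cat("  expression: ", nrow(x$module_specs), " planted modules (",
      paste(x$module_specs$size, collapse = "/"), " genes) + ",
      x$n_background, " background, 4 lines x ", x$n_replicates,
      " replicates\n", sep = "")
  cat("  cohort: n = ", x$cohort_size, ", ", x$n_prognostic, "/",
      x$n_cohort_genes, " prognostic genes at log-HR ", x$planted_log_hr,
      ", censoring ", x$censoring_rate, "\n", sep = "")
  cat("  PTM: ", x$n_peptides, " backbones, ", x$n_forms, " forms\n", sep = "")
  invisible(x)
}

# Line-level base patterns for planted module eigen-profiles; standardised to
# mean 0 / SD 1 across the four lines before expansion to samples.
trait_pattern_profile <- function(pattern) {
  p <- switch(pattern,
              progression = c(1, 2, 3, 4),
              emt         = c(0, 1, 1, 0),
              metastasis  = c(0, 0, 0, 1),
              tumor       = c(0, 0, 1, 1),
              stop("unknown trait pattern: ", pattern, call. = FALSE))
  as.numeric(scale(p))
}

sample_metadata <- function(n_replicates) {
  lines <- cell_lines()
  data.frame(
    sample = paste0(rep(c("MA", "4C", "4C11n", "4C11p"), each = n_replicates),
                    "_r", seq_len(n_replicates)),
    cell_line = factor(rep(lines, each = n_replicates), levels = lines),
    replicate = rep(seq_len(n_replicates), times = 4),
    stringsAsFactors = FALSE)
}

#' Simulate a log-scale expression matrix with planted modules
#'
#' Generates a genes x samples matrix for the fixed four-line panel. Each
#' planted module m has an eigen-profile: its line-level trait pattern
#' (or, for `"null"` modules, an independent standard-normal profile) expanded
#' to samples plus `profile_noise_sd` jitter. Member gene g is
#' `loading_g * eigenprofile + N(0, noise_sd)`, with loadings lognormal around
#' `loading_mean`. Background genes are pure `N(0, 1)` noise. Samples are
#' ordered in melan-a, 4C, 4C11-, 4C11+ blocks.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (genes x samples matrix), `meta` (sample metadata:
#'   sample, cell_line, replicate) and `truth` (ground-truth list: per-gene
#'   module and loading, per-module trait pattern).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 101L))
  specs <- config$module_specs
  meta <- sample_metadata(config$n_replicates)
  n_s <- nrow(meta)
  stop_if(sum(specs$size) > config$n_genes, "module sizes exceeding n_genes")
  n_genes <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  expr <- matrix(NA_real_, n_genes, n_s, dimnames = list(gene_ids, meta$sample))
  module_of <- rep("background", n_genes)
  loading <- rep(NA_real_, n_genes)
  idx <- 0L
  for (m in seq_len(nrow(specs))) {
    sz <- specs$size[m]
    pat <- specs$trait_pattern[m]
    if (pat == "null") {
      prof <- stats::rnorm(n_s)
    } else {
      prof <- specs$sign[m] * rep(trait_pattern_profile(pat),
                                  each = config$n_replicates)
    }
    prof <- prof + stats::rnorm(n_s, 0, config$profile_noise_sd)
    l <- stats::rlnorm(sz, meanlog = log(specs$loading_mean[m]),
                       sdlog = config$loading_sdlog)
    noise <- matrix(stats::rnorm(sz * n_s, 0, specs$noise_sd[m]), sz, n_s)
    rows <- idx + seq_len(sz)
    expr[rows, ] <- outer(l, prof) + noise
    module_of[rows] <- paste0("M", m)
    loading[rows] <- l
    idx <- idx + sz
  }
  if (config$n_background > 0) {
    rows <- idx + seq_len(config$n_background)
    expr[rows, ] <- matrix(stats::rnorm(config$n_background * n_s),
                           config$n_background, n_s)
  }
  truth <- list(
    genes = data.frame(gene = gene_ids, module = module_of, loading = loading,
                       stringsAsFactors = FALSE),
    modules = data.frame(module = paste0("M", seq_len(nrow(specs))),
                         trait_pattern = specs$trait_pattern,
                         sign = specs$sign,
                         size = specs$size, stringsAsFactors = FALSE))
  list(expr = expr, meta = meta, truth = truth)
}

#' Simulate a survival cohort under proportional hazards
#'
#' Event times follow a Weibull (default exponential) proportional-hazards
#' model whose linear predictor is the sum of `planted_log_hr` times the
#' standardised expression of each prognostic gene, plus small fixed covariate
#' effects (age, sex, tumour site, AJCC-like stage, mitotic rate). Censoring is
#' independent exponential, tuned so the expected censored fraction is
#' approximately `censoring_rate`.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (data.frame: patient, time in months, event,
#'   covariates, one column per gene) and `truth` (per-gene planted log-HR).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 202L))
  n <- config$cohort_size
  g <- config$n_cohort_genes
  genes <- sprintf("gene%03d", seq_len(g))
  beta <- rep(0, g)
  if (config$n_prognostic > 0)
    beta[seq_len(config$n_prognostic)] <- config$planted_log_hr
  x <- matrix(stats::rnorm(n * g), n, g, dimnames = list(NULL, genes))
  age <- stats::rnorm(n, 60, 12)
  sex <- factor(sample(c("female", "male"), n, replace = TRUE))
  site <- factor(sample(c("trunk", "limbs", "head_neck"), n, replace = TRUE))
  stage <- sample(1:4, n, replace = TRUE, prob = c(0.35, 0.3, 0.25, 0.1))
  mitotic_rate <- stats::rlnorm(n, 0.5, 0.6)
  lp <- drop(x %*% beta) +
    0.02 * (age - 60) + 0.2 * (sex == "male") + 0.25 * (stage - 1) +
    0.05 * (mitotic_rate - exp(0.5 + 0.18))
  shape <- config$survival_shape
  haz <- config$baseline_hazard * exp(lp)
  # inverse-CDF draw: S(t) = exp(-(haz) * t^shape) up to scale
  u <- stats::runif(n)
  t_event <- (-log(u) / haz)^(1 / shape)
  if (config$censoring_rate > 0) {
    # exponential censoring, independent of event times; rate solved so the
    # expected censored fraction E[lam_c / (lam_c + haz_i)] hits the target
    target <- config$censoring_rate
    f <- function(lc) mean(lc / (lc + haz)) - target
    lam_c <- stats::uniroot(f, lower = 1e-12, upper = 1e6,
                            tol = 1e-12)$root
    t_cens <- stats::rexp(n, rate = lam_c)^(1 / shape)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  cohort <- data.frame(patient = sprintf("P%04d", seq_len(n)),
                       time = time, event = event, age = age, sex = sex,
                       site = site, stage = stage, mitotic_rate = mitotic_rate,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(x))
  truth <- list(prognostic = data.frame(gene = genes, log_hr = beta,
                                        stringsAsFactors = FALSE))
  list(cohort = cohort, truth = truth)
}

#' PTM abundance archetypes
#'
#' The eight planted archetype profiles of relative-abundance dynamics across
#' the panel (melan-a, 4C, 4C11-, 4C11+), with the intended phenotype label of
#' each: three progression shapes (changes initiating at the pre-malignant 4C
#' step, stable across the final metastatic step), two EMT shapes (epithelial
#' vs mesenchymal V-profiles) and three metastasis shapes (change confined to
#' the 4C11- to 4C11+ step).
#'
#' @return data.frame with columns `archetype`, `label` and one column per
#'   cell line giving the positive abundance multiplier.
#' @export
ptm_archetypes <- function() {
  a <- rbind(
    prog_early_loss   = c(1.00, 0.50, 0.50, 0.50),
    prog_early_gain   = c(0.40, 1.00, 1.00, 1.00),
    prog_dip_recovery = c(1.00, 0.35, 0.80, 0.80),
    emt_epithelial    = c(1.00, 0.44, 0.44, 1.00),
    emt_mesenchymal   = c(0.44, 1.00, 1.00, 0.44),
    met_up            = c(0.50, 0.45, 0.40, 1.15),
    met_down          = c(1.05, 1.08, 1.12, 0.40),
    met_surge         = c(0.90, 1.00, 1.10, 1.85))
  out <- data.frame(archetype = rownames(a),
                    label = c("progression", "progression", "progression",
                              "EMT", "EMT",
                              "metastasis", "metastasis", "metastasis"),
                    a, row.names = NULL, stringsAsFactors = FALSE)
  names(out)[3:6] <- cell_lines()
  out
}

# Synthetic histone backbones: histone, residue range, and the lysine
# positions available for marks. Recycled as needed to reach n_peptides.
ptm_backbones <- function(n_peptides) {
  base <- list(
    list(histone = "H3.1", start = 3L,  end = 8L,   k = c(4L)),
    list(histone = "H3.1", start = 9L,  end = 17L,  k = c(9L, 14L)),
    list(histone = "H3.1", start = 18L, end = 26L,  k = c(18L, 23L)),
    list(histone = "H3.1", start = 27L, end = 40L,  k = c(27L, 36L)),
    list(histone = "H3.3", start = 27L, end = 40L,  k = c(27L, 36L)),
    list(histone = "H3.1", start = 54L, end = 63L,  k = c(56L)),
    list(histone = "H3.1", start = 73L, end = 83L,  k = c(79L)),
    list(histone = "H4",   start = 4L,  end = 17L,  k = c(5L, 8L, 12L, 16L)),
    list(histone = "H4",   start = 20L, end = 23L,  k = c(20L)),
    list(histone = "H2A",  start = 4L,  end = 11L,  k = c(5L, 9L)),
    list(histone = "H2A.Z", start = 1L, end = 19L,  k = c(4L, 7L, 11L)),
    list(histone = "H2B",  start = 1L,  end = 5L,   k = c(5L)))
  out <- vector("list", n_peptides)
  for (i in seq_len(n_peptides)) {
    b <- base[[(i - 1L) %% length(base) + 1L]]
    copy <- (i - 1L) %/% length(base)
    if (copy > 0) {                       # shift ranges to keep backbones unique
      off <- 40L * copy
      b$start <- b$start + off; b$end <- b$end + off; b$k <- b$k + off
    }
    out[[i]] <- b
  }
  out
}

#' Simulate a histone PTM peptide-area table
#'
#' Builds `n_peptides` peptide backbones carrying in total `n_forms` forms
#' (each backbone has one unmodified form plus modified forms). Each modified
#' form is assigned one of the eight [ptm_archetypes()]; its target relative
#' abundance across samples is the archetype profile scaled by a per-form
#' weight, and the unmodified form absorbs the remainder so relative abundances
#' sum to 1 per (histone, backbone, sample). Areas are the target ratios times
#' a per-sample total area times lognormal replicate noise.
#'
#' Acetylation-carrying forms are drawn from the archetypes whose profiles dip
#' at the 4C step, and methylation-only forms from the remaining archetypes, so
#' the panel-level pattern of a global acetylation drop (and methylation gain)
#' in the pre-malignant line is planted by construction.
#'
#' @param config a [sim_config()].
#' @return list with `ptm` (data.frame in the canonical PTM table layout:
#'   histone, start, end, modifications, one area column per sample), `meta`
#'   (sample metadata) and `truth` (per-form archetype and intended label;
#'   unmodified forms have `NA` archetype).
#' @export
simulate_ptm_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 303L))
  arch <- ptm_archetypes()
  meta <- sample_metadata(config$n_replicates)
  n_s <- nrow(meta)
  backbones <- ptm_backbones(config$n_peptides)
  n_mod <- config$n_forms - config$n_peptides   # modified forms overall
  stop_if(n_mod < 0, "n_forms < n_peptides")
  # distribute modified forms across backbones as evenly as possible
  per_bb <- rep(n_mod %/% config$n_peptides, config$n_peptides)
  extra <- n_mod %% config$n_peptides
  if (extra > 0) per_bb[seq_len(extra)] <- per_bb[seq_len(extra)] + 1L
  ac_arche <- c("prog_early_loss", "prog_dip_recovery", "emt_epithelial")
  me_arche <- setdiff(arch$archetype, ac_arche)
  marks_me <- c("me1", "me2", "me3")
  rows <- list(); tr <- list()
  for (i in seq_along(backbones)) {
    b <- backbones[[i]]
    k_forms <- per_bb[i]
    forms <- character(0); kinds <- character(0)
    # enumerate distinct modification strings for this backbone
    pool <- list()
    for (k in b$k) for (mk in c("ac", marks_me))
      pool[[length(pool) + 1L]] <- list(str = sprintf("K%d%s", k, mk),
                                        kind = if (mk == "ac") "ac" else "me")
    if (length(b$k) >= 2) {
      combos <- utils::combn(length(b$k), 2)
      for (j in seq_len(ncol(combos))) {
        k1 <- b$k[combos[1, j]]; k2 <- b$k[combos[2, j]]
        pool[[length(pool) + 1L]] <- list(
          str = sprintf("K%dme2K%dac", k1, k2), kind = "ac")
        pool[[length(pool) + 1L]] <- list(
          str = sprintf("K%dme1K%dme3", k1, k2), kind = "me")
      }
    }
    k_forms <- min(k_forms, length(pool))
    sel <- if (k_forms > 0) sample(length(pool), k_forms) else integer(0)
    mods <- vapply(pool[sel], `[[`, "", "str")
    kinds <- vapply(pool[sel], `[[`, "", "kind")
    # archetype per modified form, respecting mark class
    w_mix <- config$archetype_mix
    names(w_mix) <- arch$archetype
    arche <- character(length(mods))
    for (j in seq_along(mods)) {
      cand <- if (kinds[j] == "ac") ac_arche else me_arche
      arche[j] <- sample(cand, 1, prob = w_mix[cand])
    }
    # per-form weights scaled so the unmodified form keeps >= 10 % everywhere
    w <- if (length(mods)) stats::runif(length(mods), 0.5, 1) else numeric(0)
    prof <- if (length(mods))
      matrix(sapply(arche, function(a)
        as.numeric(arch[arch$archetype == a, cell_lines()])), nrow = 4)
    else matrix(0, 4, 0)                      # 4 lines x k forms
    if (length(mods)) {
      line_sums <- rowSums(sweep(prof, 2, w, "*"))
      w <- w * 0.9 / max(line_sums)    # unmodified form keeps >= 10 % everywhere
    }
    # target ratios per form per sample
    line_idx <- as.integer(meta$cell_line)
    target <- matrix(0, length(mods) + 1L, n_s)
    for (j in seq_along(mods))
      target[j, ] <- (w[j] * prof[, j])[line_idx]
    target[length(mods) + 1L, ] <- 1 - colSums(target[seq_len(length(mods)), ,
                                                      drop = FALSE])
    total_area <- stats::rlnorm(n_s, log(1e7), 0.2)
    noise <- matrix(stats::rlnorm((length(mods) + 1L) * n_s,
                                  0, config$ptm_noise_sdlog),
                    length(mods) + 1L, n_s)
    if (config$ptm_noise_sdlog == 0) noise[] <- 1
    areas <- target * rep(total_area, each = length(mods) + 1L) * noise
    all_mods <- c(mods, "unmod")
    rows[[i]] <- data.frame(histone = b$histone, start = b$start, end = b$end,
                            modifications = all_mods,
                            areas, stringsAsFactors = FALSE)
    names(rows[[i]])[5:(4 + n_s)] <- meta$sample
    tr[[i]] <- data.frame(
      form = paste0(b$histone, ":", b$start, "-", b$end, ":", all_mods),
      archetype = c(arche, NA_character_),
      stringsAsFactors = FALSE)
  }
  ptm <- do.call(rbind, rows)
  truth_forms <- do.call(rbind, tr)
  truth_forms$label <- arch$label[match(truth_forms$archetype, arch$archetype)]
  list(ptm = ptm, meta = meta,
       truth = list(forms = truth_forms, archetypes = arch))
}

#' Write / read ground truth as plain-text tables
#'
#' Serialises the `truth` component returned by the generators as TSV files
#' (one per table) with full double precision, and reads them back losslessly.
#'
#' @param truth list of data.frames (e.g. `$truth` from a generator).
#' @param dir directory to write into (created if needed).
#' @return `write_ground_truth` returns the directory invisibly;
#'   `read_ground_truth` returns the list of data.frames.
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(truth)) {
    df <- truth[[nm]]
    if (!is.data.frame(df)) next
    out <- df
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    utils::write.table(out, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ground_truth
#' @param numeric_cols named list: for each table, the columns to restore as
#'   doubles (defaults cover the generators' outputs).
#' @export
read_ground_truth <- function(dir,
                              numeric_cols = list(genes = "loading",
                                                  prognostic = "log_hr",
                                                  modules = "size")) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- list()
  for (f in files) {
    nm <- sub("\\.tsv$", "", basename(f))
    df <- utils::read.delim(f, stringsAsFactors = FALSE)
    for (col in intersect(numeric_cols[[nm]] %||% character(0), names(df)))
      df[[col]] <- as.numeric(df[[col]])
    out[[nm]] <- df
  }
  out
}
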