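# Median-split Kaplan-Meier/log-rank and Cox proportional-hazards analysis of
# single genes and multi-gene hub signatures, built on the survival package.

check_cohort <- function(cohort) {
  stop_if(!all(c("time", "event") %in% names(cohort)),
          "cohort needs 'time' and 'event' columns")
  stop_if(anyNA(cohort$time) || anyNA(cohort$event),
          "missing time/event values")
  stop_if(any(cohort$time <= 0), "times must be positive")
  stop_if(!all(cohort$event %in% c(0, 1)), "event must be 0/1")
  invisible(cohort)
}

#' Multi-gene signature score
#'
#' The signature score of a patient is the mean expression of the listed
#' genes, the usual summary for multi-gene hub signatures.
#'
#' @param cohort data.frame with one column per gene.
#' @param gene_list character vector of gene columns.
#' @return numeric vector, one score per patient.
#' @export
signature_score <- function(cohort, gene_list) {
  missing_g <- setdiff(gene_list, names(cohort))
  stop_if(length(missing_g) > 0,
          "gene(s) absent from cohort: ", paste(missing_g, collapse = ", "))
  rowMeans(as.matrix(cohort[, gene_list, drop = FALSE]))
}

#' Median split into high/low groups
#'
#' Dichotomises values at the median: `low` for values at or below the
#' median, `high` above it (deterministic tie rule).
#'
#' @param values numeric vector (length >= 2, not all identical).
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  stop_if(length(values) < 2, "at least 2 values are required")
  stop_if(stats::sd(values) == 0, "all values identical; no split possible")
  med <- stats::median(values)
  factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square on 1 degree of freedom, via
#' [survival::survdiff()]. `p_method = "permutation"` replaces the asymptotic
#' p-value with the exact permutation p-value over all relabellings that
#' preserve the group sizes (feasible for small cohorts; capped at
#' `max_permutations` enumerated assignments).
#'
#' @param time,event survival times (months) and 0/1 event indicators.
#' @param group two-level factor or vector.
#' @param p_method `"chisq"` (asymptotic) or `"permutation"` (exact).
#' @param max_permutations enumeration cap for the exact method.
#' @return list with `statistic`, `p`, `method` and `group_sizes`. A group
#'   with zero events triggers a warning, not an error.
#' @export
log_rank_test <- function(time, event, group,
                          p_method = c("chisq", "permutation"),
                          max_permutations = 2e5) {
  p_method <- match.arg(p_method)
  group <- factor(group)
  stop_if(nlevels(group) != 2, "exactly 2 groups are required")
  stop_if(sum(event) < 1, "at least one event is required")
  if (any(tapply(event, group, sum) == 0))
    warning("a group has zero events", call. = FALSE)
  stat_of <- function(g) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
    unname(sd_$chisq)
  }
  obs <- stat_of(group)
  if (p_method == "chisq") {
    p <- stats::pchisq(obs, df = 1, lower.tail = FALSE)
  } else {
    n <- length(group)
    n1 <- sum(group == levels(group)[1])
    stop_if(choose(n, n1) > max_permutations,
            "too many relabellings for exact enumeration")
    idx <- utils::combn(n, n1)
    stats_perm <- apply(idx, 2, function(ii) {
      g <- factor(ifelse(seq_len(n) %in% ii, levels(group)[1],
                         levels(group)[2]), levels = levels(group))
      stat_of(g)
    })
    p <- mean(stats_perm >= obs - 1e-12)
  }
  list(statistic = obs, p = p, method = p_method,
       group_sizes = table(group))
}

#' Cox proportional-hazards model with covariate presets
#'
#' Partial-likelihood fit (Efron tie handling) of one or more predictors with
#' optional adjustment covariates. The presets mirror the two multivariate
#' analyses used for primary-melanoma cohorts: `"MA1"` adjusts for age, sex
#' and tumour site; `"MA2"` additionally for AJCC stage and mitotic rate.
#'
#' @param cohort data.frame with `time`, `event`, predictors and covariates.
#' @param predictors character vector of predictor columns.
#' @param covariates character vector of adjustment columns, or `NULL`.
#' @param preset `"none"`, `"MA1"` or `"MA2"`; non-`"none"` presets override
#'   `covariates`.
#' @return object of class `cox_result`: data.frame with one row per
#'   predictor (`term`, `hr`, `ci_low`, `ci_high`, `p`, `n`, `n_events`), the
#'   [survival::coxph] fit in attribute `"fit"`.
#' @export
cox_model <- function(cohort, predictors, covariates = NULL,
                      preset = c("none", "MA1", "MA2")) {
  preset <- match.arg(preset)
  check_cohort(cohort)
  if (preset == "MA1") covariates <- c("age", "sex", "site")
  if (preset == "MA2") covariates <- c("age", "sex", "site", "stage",
                                       "mitotic_rate")
  vars <- c(predictors, covariates)
  missing_v <- setdiff(vars, names(cohort))
  stop_if(length(missing_v) > 0,
          "column(s) absent from cohort: ", paste(missing_v, collapse = ", "))
  const <- vars[vapply(cohort[vars], function(x) length(unique(x)) < 2, TRUE)]
  stop_if(length(const) > 0,
          "constant predictor(s): ", paste(const, collapse = ", "))
  fml <- stats::reformulate(c(sprintf("`%s`", predictors),
                              if (length(covariates)) sprintf("`%s`", covariates)),
                            response = "survival::Surv(time, event)")
  fit <- withCallingHandlers(
    survival::coxph(fml, data = cohort, ties = "efron"),
    warning = function(w) {
      if (grepl("Ran out of iterations", conditionMessage(w)))
        stop("Cox model did not converge: ", conditionMessage(w),
             call. = FALSE)
      # coxph itself flags likely complete separation ("coefficient may be
      # infinite"); let that warning propagate
    })
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  keep <- grep(paste0("^`?(", paste(predictors, collapse = "|"), ")"),
               rownames(co))
  out <- data.frame(term = rownames(co)[keep],
                    hr = unname(co[keep, "exp(coef)"]),
                    ci_low = unname(ci[keep, "lower .95"]),
                    ci_high = unname(ci[keep, "upper .95"]),
                    p = unname(co[keep, "Pr(>|z|)"]),
                    n = sm$n, n_events = sm$nevent,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  class(out) <- c("cox_result", "data.frame")
  out
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional-hazards result (n = ", x$n[1], ", events = ",
      x$n_events[1], ")\n", sep = "")
  df <- as.data.frame(x)
  df$hr <- round(df$hr, 3); df$ci_low <- round(df$ci_low, 3)
  df$ci_high <- round(df$ci_high, 3); df$p <- signif(df$p, 3)
  print(df[, c("term", "hr", "ci_low", "ci_high", "p")], row.names = FALSE)
  invisible(x)
}

#' Gene-wise survival screen
#'
#' Per gene: either a median split with a log-rank test plus a Cox fit on the
#' binary grouping (`mode = "median_split"`, the usual cohort screening
#' procedure), or a Cox fit on the continuous expression with optional
#' covariate adjustment (`mode = "multivariate"`). The `p` column carries the
#' screen's primary p-value (log-rank for median split, Cox Wald otherwise)
#' and feeds [rank_prognostic_genes()]. Per-gene failures are recorded and the
#' screen continues.
#'
#' @param cohort data.frame with `time`, `event` and one column per gene.
#' @param genes character vector of gene columns.
#' @param mode `"median_split"` or `"multivariate"`.
#' @param covariates optional adjustment columns (multivariate mode), or a
#'   preset name `"MA1"`/`"MA2"`.
#' @return data.frame with one row per gene: `gene`, `hr`, `ci_low`,
#'   `ci_high`, `logrank_p`, `cox_p`, `p`, `n_low`, `n_high`, `error`.
#' @export
gene_wise_survival_screen <- function(cohort, genes,
                                      mode = c("median_split", "multivariate"),
                                      covariates = NULL) {
  mode <- match.arg(mode)
  check_cohort(cohort)
  preset <- "none"
  if (is.character(covariates) && length(covariates) == 1 &&
      covariates %in% c("MA1", "MA2")) {
    preset <- covariates; covariates <- NULL
  }
  one <- function(g) {
    tryCatch({
      if (mode == "median_split") {
        grp <- median_split(cohort[[g]])
        lr <- log_rank_test(cohort$time, cohort$event, grp)
        cd <- cohort; cd$..grp <- as.integer(grp == "high")
        cx <- cox_model(cd, "..grp")
        data.frame(gene = g, hr = cx$hr, ci_low = cx$ci_low,
                   ci_high = cx$ci_high, logrank_p = lr$p, cox_p = cx$p,
                   p = lr$p, n_low = sum(grp == "low"),
                   n_high = sum(grp == "high"), error = NA_character_,
                   stringsAsFactors = FALSE)
      } else {
        cx <- cox_model(cohort, g, covariates = covariates, preset = preset)
        data.frame(gene = g, hr = cx$hr[1], ci_low = cx$ci_low[1],
                   ci_high = cx$ci_high[1], logrank_p = NA_real_,
                   cox_p = cx$p[1], p = cx$p[1], n_low = NA_integer_,
                   n_high = NA_integer_, error = NA_character_,
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      data.frame(gene = g, hr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, logrank_p = NA_real_, cox_p = NA_real_,
                 p = NA_real_, n_low = NA_integer_, n_high = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  suppressWarnings(do.call(rbind, lapply(genes, one)))
}
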