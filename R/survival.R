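## Kaplan-Meier estimation and log-rank association of marker expression
## with outcome. Estimation goes through the survival package; results are
## returned in plain tables so downstream steps and reports stay simple.

validate_surv <- function(surv) {
  need <- c("sample", "time", "event")
  if (!all(need %in% names(surv))) {
    abort("survival table needs columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(surv$sample)) abort("duplicated sample ids")
  if (any(!is.finite(surv$time)) || any(surv$time <= 0)) {
    abort("times must be positive and finite")
  }
  if (!all(surv$event %in% c(0, 1))) abort("event flags must be 0/1")
  surv
}

#' Kaplan-Meier product-limit estimate
#'
#' Ties between events and censorings at the same time follow the standard
#' convention (events precede censorings). With no events the estimate is
#' identically 1.
#'
#' @param surv data.frame sample, time (> 0), event (0/1).
#' @return data.frame time, n_risk, n_event, n_censor, surv; S(0) = 1 is
#'   implicit (the first row starts from the earliest observed time).
#' @export
km_estimate <- function(surv) {
  surv <- validate_surv(surv)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv)
  data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df, two-sided p). The hazard-ratio
#' estimate is the observed/expected ratio (O1/E1)/(O2/E2) for the first
#' stratum level versus the second; expected counts are checked to conserve
#' the total number of events on every call.
#'
#' @param surv data.frame sample, time, event.
#' @param strata named sample -> two-level stratum vector (e.g. "high" /
#'   "low").
#' @return list with chisq, p, hazard_ratio, and a per-stratum table
#'   (n, observed, expected).
#' @export
logrank_test <- function(surv, strata) {
  surv <- validate_surv(surv)
  if (is.null(names(strata))) abort("strata must be named by sample")
  surv <- surv[surv$sample %in% names(strata), , drop = FALSE]
  surv$stratum <- factor(strata[surv$sample])
  if (nlevels(surv$stratum) != 2L) {
    abort("exactly 2 non-empty strata are required (got ",
          nlevels(droplevels(surv$stratum)), ")")
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ stratum,
                            data = surv)
  obs <- sd_$obs; expd <- sd_$exp
  stopifnot(abs(sum(obs) - sum(expd)) < 1e-8)  # event-count conservation
  hr <- (obs[1L] / expd[1L]) / (obs[2L] / expd[2L])
  list(
    chisq = unname(sd_$chisq),
    p = stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE),
    hazard_ratio = unname(hr),
    strata = data.frame(
      stratum = levels(surv$stratum),
      n = as.vector(sd_$n), observed = obs, expected = expd
    )
  )
}

#' Log-rank association of a marker gene with survival
#'
#' Dichotomizes the cohort at the median expression of `gene` (ties at the
#' median go to the low stratum) and runs [logrank_test()]. The cut value
#' and stratum sizes are recorded with the result.
#'
#' @param expr gene x sample matrix.
#' @param gene gene id (must be non-constant).
#' @param surv data.frame sample, time, event (>= 4 samples shared with the
#'   matrix).
#' @param quantile_cut stratification quantile (default 0.5, the median).
#' @return [logrank_test()] result plus `gene`, `cut_value`, `stratum_of`.
#' @export
marker_survival_analysis <- function(expr, gene, surv, quantile_cut = 0.5) {
  if (!gene %in% rownames(expr)) abort("gene ", gene, " not in the matrix")
  surv <- validate_surv(surv)
  shared <- intersect(colnames(expr), surv$sample)
  if (length(shared) < 4L) abort("fewer than 4 samples with outcomes")
  x <- expr[gene, shared]
  if (stats::sd(x) == 0) abort("gene ", gene, " is constant in the cohort")
  cut <- stats::quantile(x, quantile_cut, names = FALSE)
  strata <- stats::setNames(ifelse(x > cut, "high", "low"), shared)
  res <- logrank_test(surv[surv$sample %in% shared, , drop = FALSE], strata)
  res$gene <- gene
  res$cut_value <- cut
  res$stratum_of <- strata
  res
}
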