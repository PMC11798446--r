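#' Rank AUC of a single gene
#'
#' The probability that a randomly chosen case sample has a higher value
#' than a randomly chosen control (ties count one half), computed by pair
#' counting via the rank-sum identity. For a single covariate this equals
#' the ROC AUC of the univariate logistic model, since the logistic score is
#' monotone in the covariate.
#'
#' @param values Numeric expression values.
#' @param groups `"case"`/`"control"` label per value.
#' @return List: `auc`, `n_case`, `n_control`.
#' @export
#' @examples
#' auc_single_gene(c(1, 3, 2, 4),
#'                 c("case", "case", "control", "control"))$auc # 0.25
auc_single_gene <- function(values, groups) {
  case <- values[groups == "case"]
  ctrl <- values[groups == "control"]
  if (length(case) == 0 || length(ctrl) == 0) {
    stopf("both groups must be non-empty")
  }
  r <- rank(c(case, ctrl), ties.method = "average")
  u <- sum(r[seq_along(case)]) - length(case) * (length(case) + 1) / 2
  list(auc = u / (length(case) * length(ctrl)),
       n_case = length(case), n_control = length(ctrl))
}

#' Per-gene AUC table
#'
#' @param expr Gene x sample matrix.
#' @param groups Per-sample labels.
#' @param genes Genes to evaluate; default all rows.
#' @return Tibble `gene`, `auc`, `n_case`, `n_control`.
#' @export
auc_by_gene <- function(expr, groups, genes = rownames(expr)) {
  purrr::map_dfr(genes, function(g) {
    if (!g %in% rownames(expr)) {
      return(tibble(gene = g, auc = NA_real_, n_case = NA_integer_,
                    n_control = NA_integer_))
    }
    r <- auc_single_gene(as.numeric(expr[g, ]), groups)
    tibble(gene = g, auc = r$auc, n_case = r$n_case, n_control = r$n_control)
  })
}

#' Median split into risk groups
#'
#' Values strictly above the cohort median go to `"high"`; values at or
#' below it to `"low"`.
#'
#' @param x Numeric expression per sample.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(x) {
  if (length(x) < 2) stopf("need at least 2 samples")
  if (length(unique(x)) == 1) stopf("all values identical; degenerate split")
  m <- median(x)
  factor(ifelse(x > m, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate per group: `S(t)` multiplies `(1 - d_i/n_i)` over
#' event times up to `t`; censored subjects leave the risk set after their
#' time.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 event, 0 censored).
#' @param group Optional group per subject (single group when omitted).
#' @return Tibble: `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time < 0)) stopf("negative survival time")
  group <- group %||% rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = group))
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group)[1], length(s$time))
         else sub("^g=", "", as.character(s$strata))
  tibble(group = grp, time = s$time, n_risk = s$n.risk,
         n_event = s$n.event, surv = s$surv)
}

#' Log-rank test between two groups
#'
#' At each event time the observed-minus-expected event count in group A and
#' its hypergeometric variance are accumulated;
#' `chi_sq = (sum(O - E))^2 / sum(V)` is referred to a chi-squared
#' distribution with 1 df.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level group per subject.
#' @return List: `chi_sq`, `p`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  if (sum(event) < 1) stopf("no events observed")
  if (length(unique(group)) != 2) stopf("log-rank test needs two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = group))
  list(chi_sq = as.numeric(sd$chisq),
       p = pchisq(as.numeric(sd$chisq), df = 1, lower.tail = FALSE),
       observed = as.numeric(sd$obs), expected = as.numeric(sd$exp))
}

#' Univariate Cox proportional hazards fit
#'
#' Partial-likelihood maximization with Breslow tie handling; the hazard
#' ratio is the exponentiated coefficient.
#'
#' @param time,event Follow-up times and event indicators.
#' @param covariate Numeric covariate (e.g. expression, or a 0/1 group).
#' @return Tibble: `beta`, `hr`, `se`, `wald_p`, `ci_low`, `ci_high`
#'   (95% CI on the hazard ratio), `converged`.
#' @export
cox_univariate <- function(time, event, covariate) {
  if (sum(event) < 1) stopf("no events observed")
  if (length(unique(covariate)) < 2) stopf("constant covariate")
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                    data = data.frame(time = time, event = event,
                                      x = as.numeric(covariate))),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                        data = data.frame(time = time, event = event,
                                          x = as.numeric(covariate))))
      attr(f, "flagged") <- conditionMessage(w)
      f
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  converged <- is.null(attr(fit, "flagged")) && is.finite(beta) &&
    is.finite(se) && se < 1e3
  tibble(beta = beta, hr = exp(beta), se = se,
         wald_p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
         ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
         converged = converged)
}

#' Validate candidate genes: discriminative and prognostic metrics
#'
#' Per gene: rank AUC on a case/control dataset, and on a survival cohort a
#' median-split log-rank test plus a univariate Cox fit on continuous
#' expression.
#'
#' @param genes Gene symbols.
#' @param expr Gene x sample case/control expression matrix (for AUC);
#'   `NULL` to skip.
#' @param groups Per-sample labels matching `expr`.
#' @param survival_cohort List with `clinical` (tibble `sample`, `time`,
#'   `event`) and `expression` (gene x sample matrix), as produced by
#'   [generate_survival_cohort()]; `NULL` to skip.
#' @return Tibble: `gene`, `auc`, `hr`, `ci_low`, `ci_high`, `cox_p`,
#'   `logrank_p`.
#' @export
validate_genes <- function(genes, expr = NULL, groups = NULL,
                           survival_cohort = NULL) {
  genes <- normalize_symbols(genes)
  out <- tibble(gene = genes)
  if (!is.null(expr)) {
    out <- left_join(out, auc_by_gene(expr, groups, genes)[, c("gene", "auc")],
                     by = "gene")
  } else {
    out$auc <- NA_real_
  }
  if (!is.null(survival_cohort)) {
    cl <- survival_cohort$clinical
    sx <- survival_cohort$expression
    surv_stats <- purrr::map_dfr(genes, function(g) {
      if (!g %in% rownames(sx)) {
        return(tibble(gene = g, hr = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, cox_p = NA_real_,
                      logrank_p = NA_real_))
      }
      x <- as.numeric(sx[g, cl$sample])
      cox <- cox_univariate(cl$time, cl$event, x)
      lr <- logrank_test(cl$time, cl$event, median_split(x))
      tibble(gene = g, hr = cox$hr, ci_low = cox$ci_low,
             ci_high = cox$ci_high, cox_p = cox$wald_p, logrank_p = lr$p)
    })
    out <- left_join(out, surv_stats, by = "gene")
  }
  out
}
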