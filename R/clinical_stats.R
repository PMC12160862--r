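# Clinical statistics layer: composite IHC scoring, contingency tests,
# Kaplan-Meier / log-rank, Cox proportional hazards, and in-vitro/in-vivo
# assay formulas.

#' Composite immunohistochemistry score
#'
#' The stained-area percentage is binned to an area score using half-open
#' bins `[0,5], (5,25], (25,50], (50,75], (75,100]` (scores 0-4) and
#' multiplied by the intensity grade (0-3), giving a composite score from 0
#' to 12. Categories: composite >= 6 is `high`, 3-5 `low`, <= 2 `negative`
#' (a score of exactly 6 is assigned to `high`, matching the dichotomized
#' high/low analysis where high means score >= 6).
#'
#' @param area_percent stained area in `[0, 100]` (vectorized).
#' @param intensity_grade integer grade 0-3 (vectorized).
#' @return data.frame with `area_percent`, `intensity_grade`, `area_score`,
#'   `composite`, `category` (factor negative/low/high).
#' @export
ihc_composite_score <- function(area_percent, intensity_grade) {
  if (any(!is.finite(area_percent)) || any(area_percent < 0 | area_percent > 100))
    stop("area_percent must lie in [0, 100]", call. = FALSE)
  if (any(!intensity_grade %in% 0:3))
    stop("intensity_grade must be an integer 0-3", call. = FALSE)
  area_score <- findInterval(area_percent, c(5, 25, 50, 75), left.open = TRUE)
  composite <- area_score * intensity_grade
  category <- cut(composite, breaks = c(-Inf, 2, 5, Inf),
                  labels = c("negative", "low", "high"))
  data.frame(area_percent = area_percent, intensity_grade = intensity_grade,
             area_score = area_score, composite = composite,
             category = category)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction (the variant that
#' reproduces the printed cohort p-values), with expected counts under
#' independence and `df = (r - 1)(c - 1)`. A Yates-corrected variant is
#' available behind `correct = TRUE`.
#'
#' @param table r x c matrix of non-negative integer counts with positive
#'   margins (>= 2 rows and columns).
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need at least a 2 x 2 table", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in contingency table", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Kaplan-Meier curves with a log-rank comparison
#'
#' Product-limit survival estimate per group plus the log-rank test
#' (observed vs expected events aggregated over distinct event times),
#' referred to a chi-square distribution with `groups - 1` degrees of
#' freedom.
#'
#' @param time non-negative follow-up times.
#' @param event event indicator (1/TRUE = event, 0/FALSE = censored); at
#'   least one event overall.
#' @param groups group label per subject; every group must be non-empty.
#' @return a `km_logrank` list: `fit` (a [survival::survfit] object),
#'   `curves` (data.frame of time, survival, at-risk per group),
#'   `statistic`, `df`, `p_value`.
#' @export
km_logrank <- function(time, event, groups) {
  stopifnot(all(time >= 0), length(time) == length(event),
            length(time) == length(groups))
  event <- as.integer(as.logical(event))
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  groups <- as.factor(as.character(groups))
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)

  srv <- survival::Surv(time, event)
  fit <- survival::survfit(srv ~ groups)
  curves <- data.frame(time = fit$time, survival = fit$surv,
                       at_risk = fit$n.risk,
                       group = rep(sub("^groups=", "",
                                       names(fit$strata) %||% levels(groups)[1]),
                                   fit$strata %||% length(fit$time)))
  if (nlevels(groups) < 2) {
    return(structure(list(fit = fit, curves = curves, statistic = NA_real_,
                          df = NA_integer_, p_value = NA_real_),
                     class = "km_logrank"))
  }
  lr <- survival::survdiff(srv ~ groups)
  df <- nlevels(groups) - 1L
  structure(list(fit = fit, curves = curves,
                 statistic = unname(lr$chisq), df = df,
                 p_value = stats::pchisq(lr$chisq, df, lower.tail = FALSE)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> chi-square %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood fit (Breslow tie handling) with Wald confidence
#' intervals and p-values per covariate.
#'
#' @param records data.frame with columns `time`, `event`, and the
#'   covariates.
#' @param covariates character vector of covariate column names; none may be
#'   constant.
#' @return data.frame with `term`, `hr`, `ci_lower`, `ci_upper`, `p_value`,
#'   with the fitted [survival::coxph] model attached as attribute `"fit"`.
#' @export
cox_ph <- function(records, covariates) {
  stopifnot(all(c("time", "event") %in% names(records)),
            all(covariates %in% names(records)))
  if (sum(records$event) < 1) stop("need at least one event", call. = FALSE)
  for (v in covariates) {
    x <- records[[v]]
    if (length(unique(x[!is.na(x)])) < 2)
      stop(sprintf("covariate `%s` is constant: non-identifiable", v),
           call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "breslow")
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    stop("Cox fit did not converge", call. = FALSE)
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p_value = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' In-vitro and in-vivo assay formulas
#'
#' Applies the standard bench formulas: xenograft tumor volume
#' `0.5 x length x width^2`; wound healing
#' `(1 - current area / initial area) x 100` percent (a widening wound
#' reports negative healing with a warning); colony formation rate
#' `colonies / seeded cells x 100` percent.
#'
#' @param kind `"volume"`, `"wound"`, or `"colony"`.
#' @param ... for `volume`: `length`, `width`; for `wound`: `initial_area`,
#'   `current_area`; for `colony`: `colonies`, `seeded`.
#' @return scalar metric (mm^3 for volume, percent otherwise).
#' @export
assay_metrics <- function(kind = c("volume", "wound", "colony"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  switch(kind,
    volume = {
      stopifnot(args$length > 0, args$width > 0)
      0.5 * args$length * args$width^2
    },
    wound = {
      stopifnot(args$initial_area > 0)
      pct <- (1 - args$current_area / args$initial_area) * 100
      if (pct < 0) warning("current wound area exceeds initial area; negative healing")
      pct
    },
    colony = {
      stopifnot(args$seeded > 0)
      args$colonies / args$seeded * 100
    })
}
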