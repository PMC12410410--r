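#' Split samples into risk groups by predicted odds
#'
#' Converts each sample's predicted response probability `p` to odds
#' `p / (1 - p)`, takes the arithmetic mean of the odds as the cohort
#' threshold, and assigns samples with odds strictly greater than the mean
#' to the low-risk group, all others to the high-risk group. (Responders are
#' expected to live longer, hence high response odds map to *low* risk.) A
#' probability of exactly 1 gives infinite odds: such samples are forced
#' low-risk and excluded from the mean, with a warning. Note the threshold
#' is always recomputed from the probabilities supplied, so any monotone
#' rescaling of the probabilities changes the split unless it preserves the
#' mean-odds cutpoint.
#'
#' @param probabilities Named numeric vector of response probabilities in
#'   `[0, 1]` (names = sample IDs).
#' @return Object of class `risk_assignment`: data.frame with columns
#'   `sample_id`, `probability`, `odds`, `group` (`"low-risk"` /
#'   `"high-risk"`); attribute `threshold` = mean odds.
#' @export
risk_split <- function(probabilities) {
  if (is.null(names(probabilities))) {
    names(probabilities) <- paste0("sample", seq_along(probabilities))
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  inf <- probabilities == 1
  odds <- ifelse(inf, Inf, probabilities / (1 - probabilities))
  if (any(inf)) {
    warning(sum(inf), " sample(s) with p = 1 forced low-risk and excluded ",
            "from the mean odds", call. = FALSE)
  }
  threshold <- mean(odds[!inf])
  group <- ifelse(inf | odds > threshold, "low-risk", "high-risk")
  out <- data.frame(sample_id = names(probabilities),
                    probability = unname(probabilities),
                    odds = unname(odds),
                    group = factor(group, levels = c("low-risk", "high-risk")),
                    stringsAsFactors = FALSE)
  structure(out, class = c("risk_assignment", "data.frame"),
            threshold = threshold)
}

match_survival <- function(assignment, surv) {
  missing <- setdiff(assignment$sample_id, surv$sample_id)
  if (length(missing) > 0L) {
    stop("sample(s) missing survival data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hit <- match(assignment$sample_id, surv$sample_id)
  data.frame(sample_id = assignment$sample_id,
             group = assignment$group,
             time = surv$time[hit],
             event = surv$event[hit],
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves and two-sided log-rank test between risk groups
#'
#' @param assignment A `risk_assignment` from [risk_split()].
#' @param surv Survival table (see [read_survival()]).
#' @return List with `p_value` (two-sided log-rank), `statistic` (log-rank
#'   chi-squared), and `km` (data.frame `time`, `survival`, `group` of the
#'   Kaplan-Meier estimates per group).
#' @export
km_logrank <- function(assignment, surv) {
  d <- match_survival(assignment, surv)
  if (any(table(d$group) == 0L)) {
    stop("both risk groups must be nonempty for the log-rank test",
         call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata <- rep(names(sf$strata), sf$strata)
  km <- data.frame(time = sf$time, survival = sf$surv,
                   group = sub("^group=", "", strata),
                   stringsAsFactors = FALSE)
  list(p_value = p, statistic = sd$chisq, km = km)
}

#' Univariate Cox hazard ratio of high- vs low-risk group
#'
#' Fits a univariate Cox proportional hazards model with the risk group as
#' the only covariate (low-risk as reference), returning the hazard ratio of
#' the high-risk group with its 95% confidence interval.
#'
#' @inheritParams km_logrank
#' @return Object of class `survival_stats`: list with `hazard_ratio`,
#'   `ci_lower`, `ci_upper`, `p_value`, `n_low`, `n_high`, `n_events`.
#' @export
cox_hr <- function(assignment, surv) {
  d <- match_survival(assignment, surv)
  if (any(table(d$group) == 0L)) {
    stop("both risk groups must be nonempty for the Cox model", call. = FALSE)
  }
  if (sum(d$event) == 0L) stop("no events in survival data", call. = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ group, data = d)
  s <- summary(fit)
  structure(list(hazard_ratio = unname(s$conf.int[1L, "exp(coef)"]),
                 ci_lower = unname(s$conf.int[1L, "lower .95"]),
                 ci_upper = unname(s$conf.int[1L, "upper .95"]),
                 p_value = unname(s$coefficients[1L, "Pr(>|z|)"]),
                 n_low = sum(d$group == "low-risk"),
                 n_high = sum(d$group == "high-risk"),
                 n_events = sum(d$event)),
            class = "survival_stats")
}

#' @export
print.survival_stats <- function(x, ...) {
  cat(sprintf("HR (high vs low risk) = %.3f [95%% CI %.3f-%.3f], p = %.3g (%d/%d samples, %d events)\n",
              x$hazard_ratio, x$ci_lower, x$ci_upper, x$p_value,
              x$n_low, x$n_high, x$n_events))
  invisible(x)
}

#' Write Kaplan-Meier curves as TSV
#'
#' @param km The `km` data.frame from [km_logrank()].
#' @param path Output path.
#' @export
write_km_curves <- function(km, path) {
  utils::write.table(km, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
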