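#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' the distinct event times, with right censoring; tied events precede
#' tied censorings at the same time (the standard convention). Backed by
#' [survival::survfit].
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event observed, 0 = censored).
#' @param group_name Name attached to the curve.
#' @return An object of class `survival_curve`: list with `group_name`,
#'   `event_times` (distinct, increasing), `survival_prob` (step values
#'   after each event time), `n_at_risk` (just before each event time),
#'   `n`, and `censor_times`.
#' @export
km_estimate <- function(times, events, group_name = "group") {
  if (length(times) == 0) stop("empty survival input")
  if (length(times) != length(events))
    stop("times and events differ in length")
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  has_event <- fit$n.event > 0
  structure(list(group_name = group_name,
                 event_times = fit$time[has_event],
                 survival_prob = fit$surv[has_event],
                 n_at_risk = fit$n.risk[has_event],
                 n = length(times),
                 censor_times = sort(times[events == 0])),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> %s: n=%d, %d event times, final S=%.4f\n",
              x$group_name, x$n, length(x$event_times),
              if (length(x$survival_prob)) min(x$survival_prob) else 1))
  invisible(x)
}

#' Log-rank test between two or more groups
#'
#' Standard (unweighted) log-rank test: at each distinct event time the
#' expected events per group follow the hypergeometric model, and the
#' statistic is the quadratic form of observed-minus-expected totals in
#' the inverse of their covariance, referred to a chi-squared distribution
#' with `G - 1` degrees of freedom. Backed by [survival::survdiff].
#'
#' @param groups List of groups, each a list with elements `times`,
#'   `events` and `name`.
#' @return An object of class `logrank_result`: list with `statistic`,
#'   `df`, `p_value`, `groups` (names + sizes), `observed` and `expected`
#'   per-group event counts.
#' @export
logrank_test <- function(groups) {
  if (length(groups) < 2) stop("log-rank test needs at least 2 groups")
  sizes <- vapply(groups, function(g) length(g$times), integer(1))
  if (any(sizes == 0)) stop("empty group in log-rank test")
  nms <- vapply(seq_along(groups), function(i)
    groups[[i]]$name %||% paste0("group", i), character(1))
  if (anyDuplicated(nms))
    stop("duplicated group name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  df_all <- data.frame(
    time = unlist(lapply(groups, `[[`, "times")),
    event = unlist(lapply(groups, `[[`, "events")),
    group = factor(rep(nms, sizes), levels = nms))
  if (sum(df_all$event) == 0)
    stop("no events in any group; log-rank statistic undefined")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = df_all)
  df <- length(groups) - 1L
  structure(list(statistic = unname(fit$chisq),
                 df = df,
                 p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
                 groups = data.frame(name = nms, n = sizes),
                 observed = unname(fit$obs),
                 expected = unname(fit$exp)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-squared = %.4f on %d df, p = %s\n",
              x$statistic, x$df, format(x$p_value, digits = 5,
                                        scientific = TRUE)))
  invisible(x)
}

#' Compare subgroup survival: KM curves plus a joint log-rank test
#'
#' Resolves each subgroup selection against the clinical table, fits one
#' Kaplan-Meier curve per subgroup and runs a joint log-rank test.
#' Selections must be pairwise disjoint; members without a clinical row
#' are dropped with a message (a selection losing all members is an
#' error).
#'
#' @param clin A `clinical_table` (see [load_clinical]).
#' @param selections List of `subgroup_selection` objects (length >= 2).
#' @return List with `curves` (one `survival_curve` per selection) and
#'   `test` (a `logrank_result`).
#' @export
compare_subgroups <- function(clin, selections) {
  if (length(selections) < 2)
    stop("need at least 2 subgroups to compare")
  ids <- lapply(selections, `[[`, "member_ids")
  all_ids <- unlist(ids)
  if (anyDuplicated(all_ids)) {
    shared <- unique(all_ids[duplicated(all_ids)])
    stop("subgroup selections overlap; shared sample(s): ",
         paste(utils::head(shared, 10), collapse = ", "))
  }
  groups <- list()
  curves <- list()
  for (s in selections) {
    rows <- match(s$member_ids, clin$sample_id)
    n_miss <- sum(is.na(rows))
    if (n_miss > 0)
      message("subgroup '", s$name, "': dropping ", n_miss,
              " member(s) without clinical rows")
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0)
      stop("subgroup '", s$name, "' has no members with clinical data")
    g <- list(times = clin$survival_time[rows],
              events = clin$event_status[rows], name = s$name)
    groups[[length(groups) + 1L]] <- g
    curves[[s$name]] <- km_estimate(g$times, g$events, s$name)
  }
  list(curves = curves, test = logrank_test(groups))
}

#' Write a subgroup survival comparison to JSON and CSV
#'
#' The JSON carries each curve as step-function arrays plus the log-rank
#' statistic, df and p-value (full double precision); the CSV holds the
#' stacked per-group step functions.
#'
#' @param comparison Result of [compare_subgroups].
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_survival_comparison <- function(comparison, json_path = NULL,
                                      csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(
      curves = lapply(comparison$curves, function(cv)
        list(group = cv$group_name, n = cv$n,
             event_times = cv$event_times,
             survival_prob = cv$survival_prob,
             n_at_risk = cv$n_at_risk,
             censor_times = cv$censor_times)),
      logrank = list(statistic = comparison$test$statistic,
                     df = comparison$test$df,
                     p_value = comparison$test$p_value,
                     observed = comparison$test$observed,
                     expected = comparison$test$expected,
                     groups = comparison$test$groups))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(comparison$curves, function(cv) {
      if (length(cv$event_times) == 0) return(NULL)
      data.frame(group = cv$group_name, time = cv$event_times,
                 survival = cv$survival_prob, n_at_risk = cv$n_at_risk)
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(json = json_path, csv = csv_path))
}
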