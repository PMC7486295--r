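#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimate `S(t_i) = prod_{j <= i} (1 - d_j / n_j)` over the
#' observed times, computed through [survival::survfit()]. Censored
#' observations tied with events at the same time remain at risk through the
#' event (standard product-limit tie convention).
#'
#' @param table a `survival_table`
#' @param group optional group label; `NULL` uses every row
#' @param conf whether to attach Greenwood standard errors, default `FALSE`
#' @return `data.frame` of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (plus `std_err` when `conf = TRUE`)
#' @export
km_estimate <- function(table, group = NULL, conf = FALSE) {
  stopifnot(inherits(table, "survival_table"))
  if (!is.null(group)) table <- table[table$group %in% group, , drop = FALSE]
  if (nrow(table) == 0) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(table), conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  if (conf) out$std_err <- fit$std.err * fit$surv
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Mantel-Cox log-rank test between patient groups
#'
#' At every event time the observed events per group are compared with
#' hypergeometric expectations given the risk sets; the resulting chi-square
#' statistic has `groups - 1` degrees of freedom. Computed through
#' [survival::survdiff()].
#'
#' @param table a `survival_table` whose `group` column has at least two
#'   non-empty levels and at least one event overall
#' @return list with `chi_square`, `df`, `p`, `n_groups`
#' @export
logrank_test <- function(table) {
  stopifnot(inherits(table, "survival_table"))
  tab <- table[!is.na(table$group), , drop = FALSE]
  if (length(unique(tab$group)) < 2)
    stop("need >= 2 non-empty groups for a log-rank test")
  if (sum(tab$event) == 0) stop("no events; log-rank test undefined")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = as.data.frame(tab))
  df <- length(sd_fit$n) - 1L
  list(chi_square = as.numeric(sd_fit$chisq), df = df,
       p = pchisq(as.numeric(sd_fit$chisq), df, lower.tail = FALSE),
       n_groups = length(sd_fit$n))
}

#' Significance stars for p-values
#'
#' The reporting convention `*`, `**`, `***`, `****` for p <= 0.05, 0.01,
#' 0.001, 0.0001 (`"ns"` above 0.05).
#'
#' @param p numeric p-values
#' @return character vector of annotations
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}
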