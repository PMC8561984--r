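#' Unit cost per service from a cost ledger
#'
#' Average cost: total provider spending on the service divided by total
#' units (visits or admissions) delivered in the same period.
#'
#' @param ledger a [cost_ledger()].
#' @return named numeric vector, service -> unit cost.
#' @export
unit_costs <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  bad <- ledger$total_spending > 0 & ledger$total_units <= 0
  if (any(bad))
    stop(sprintf("zero units with positive spending for: %s",
                 paste(ledger$service[bad], collapse = ", ")), call. = FALSE)
  stats::setNames(ifelse(ledger$total_units > 0,
                         ledger$total_spending / ledger$total_units, 0),
                  ledger$service)
}

#' Annualization factor for a utilization recall window
#'
#' Benefits are compared on a yearly basis; utilization reported over a
#' short recall window is scaled by period/recall. A 4-week outpatient
#' recall in a 52-week year gives the factor 13; the 12-month inpatient
#' recall gives 1.
#'
#' @param recall_weeks recall window in weeks.
#' @param period_weeks reference period (default 52, one year).
#' @return scaling factor.
#' @export
annualization_factor <- function(recall_weeks, period_weeks = 52) {
  if (recall_weeks <= 0) stop("recall_weeks must be > 0", call. = FALSE)
  period_weeks / recall_weeks
}

.default_alpha <- function() c(out_public = 13, out_private = 13,
                               inp_public = 1, inp_private = 1)

#' Individual subsidy benefits per service
#'
#' For each person and service: quantity (1 unit per positive any-use report
#' — a lower-bound utilization assumption since the survey records any use,
#' not counts), gross benefit alpha_k * q * c_k and net benefit
#' alpha_k * max(q * c_k - oop, 0). Negative net benefits (out-of-pocket
#' exceeding the service's unit cost) are truncated to zero. Services absent
#' from the ledger get unit cost 0 (no subsidy), so out-of-pocket payments at
#' unsubsidized providers never create negative program benefits.
#'
#' @param dataset a `survey_dataset` or `ranked_dataset`.
#' @param costs named unit-cost vector from [unit_costs()] (or a
#'   `cost_ledger`).
#' @param alpha named annualization factors per service; defaults 13 for the
#'   two outpatient services (4-week recall), 1 for inpatient (12-month).
#' @return data.frame of class `benefit_records`: `person_id`, `service`,
#'   `q`, `unit_cost`, `oop`, `gross_benefit`, `net_benefit`.
#' @export
individual_benefits <- function(dataset, costs, alpha = NULL) {
  if (inherits(costs, "cost_ledger")) costs <- unit_costs(costs)
  if (is.null(alpha)) alpha <- .default_alpha()
  ind <- dataset$individuals
  rows <- lapply(.services, function(k) {
    q <- ind[[paste0("use_", k)]]
    f <- ind[[paste0("oop_", k)]]
    if (any(f < 0)) stop("negative OOP amount", call. = FALSE)
    ck <- if (k %in% names(costs)) unname(costs[k]) else 0
    ak <- if (k %in% names(alpha)) unname(alpha[k]) else 1
    data.frame(person_id = ind$person_id, service = k, q = q, unit_cost = ck,
               oop = f,
               gross_benefit = ak * q * ck,
               net_benefit = ak * pmax(q * ck - f, 0),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("benefit_records", "data.frame"))
}

#' Quintile shares and concentration of subsidy benefits
#'
#' Sums weighted gross and net benefits within consumption quintiles,
#' normalizes each service column to percentages, and attaches the plain
#' concentration index of the per-individual benefit amount (a continuous
#' variable; no binary normalization applies). Also reports each service's
#' share of total (gross) subsidies.
#'
#' @param records `benefit_records` from [individual_benefits()].
#' @param ranked a [rank_dataset()] result supplying quintiles, ranks and
#'   weights.
#' @param services which services to tabulate (default: those with any
#'   positive gross benefit).
#' @param ledger optional [cost_ledger()]; when given, the per-service share
#'   of total subsidies is taken from the ledger's spending split, otherwise
#'   from the realized weighted gross benefits.
#' @return object of class `benefit_table`: data.frame with one row per
#'   service x benefit type: `Q1`..`Q5` percentage shares, `total`, `ci`,
#'   `ci_se`, `stars`; attribute `subsidy_share` (per-service share of total
#'   subsidies, in %).
#' @export
benefit_shares <- function(records, ranked, services = NULL, ledger = NULL) {
  stopifnot(inherits(records, "benefit_records"),
            inherits(ranked, "ranked_dataset"))
  ind <- ranked$individuals
  idx <- match(records$person_id, ind$person_id)
  if (anyNA(idx))
    stop("benefit records reference persons absent from the dataset",
         call. = FALSE)
  records$quintile <- ind$quintile[idx]
  records$weight <- ind$weight[idx]
  records$frac_rank <- ind$frac_rank[idx]
  if (is.null(services)) {
    tot <- tapply(records$gross_benefit * records$weight, records$service, sum)
    services <- names(tot)[tot > 0]
  }
  rows <- list()
  for (k in services) {
    rk <- records[records$service == k, ]
    for (type in c("gross", "net")) {
      b <- if (type == "gross") rk$gross_benefit else rk$net_benefit
      tot <- sum(b * rk$weight)
      if (tot <= 0) {
        warning(sprintf("all-zero %s benefits for service %s; shares undefined",
                        type, k), call. = FALSE)
        shares <- rep(NA_real_, 5); ci <- NA_real_; se <- NA_real_; st <- ""
      } else {
        qs <- vapply(1:5, function(q)
          sum(b[rk$quintile == q] * rk$weight[rk$quintile == q]), numeric(1))
        shares <- 100 * qs / tot
        est <- concentration_index(b, rk$frac_rank, rk$weight,
                                   outcome_name = paste(k, type))
        ci <- est$index_plain; se <- est$se; st <- est$stars
      }
      rows[[paste(k, type)]] <- data.frame(
        service = k, type = type, Q1 = shares[1], Q2 = shares[2],
        Q3 = shares[3], Q4 = shares[4], Q5 = shares[5], total = tot,
        ci = ci, ci_se = se, stars = st, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(ledger)) {
    sp <- ledger$total_spending[match(services, ledger$service)]
    sp[is.na(sp)] <- 0
    share <- stats::setNames(100 * sp / sum(sp), services)
  } else {
    gross_tot <- vapply(services, function(k)
      tab$total[tab$service == k & tab$type == "gross"], numeric(1))
    share <- 100 * gross_tot / sum(gross_tot)
  }
  structure(tab, class = c("benefit_table", "data.frame"),
            subsidy_share = share)
}

#' @export
print.benefit_table <- function(x, ...) {
  cat("<benefit_table> quintile percentage shares of subsidy benefits\n")
  print.data.frame(x, digits = 4)
  ss <- attr(x, "subsidy_share")
  cat("  share of total subsidies:",
      paste(sprintf("%s=%.1f%%", names(ss), ss), collapse = " "), "\n")
  invisible(x)
}
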