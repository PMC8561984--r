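#' Wagstaff normalization of a binary-outcome concentration index
#'
#' Divides the plain index by (1 - mu) so the attainable range of a binary
#' outcome's concentration index becomes [-1, 1]; a *relative* inequality
#' measure.
#'
#' @param ci plain concentration index.
#' @param mu mean of the binary outcome, in (0, 1).
#' @return normalized index.
#' @export
wagstaff_normalize <- function(ci, mu) {
  if (any(mu >= 1) || any(mu < 0))
    stop("mu must be in [0, 1) for the Wagstaff normalization", call. = FALSE)
  ci / (1 - mu)
}

#' Erreygers correction of a bounded outcome's concentration index
#'
#' Rescales by 4*mu/(b - a) where (a, b) are the outcome's bounds; an
#' *absolute* inequality measure. For a binary outcome (a = 0, b = 1) it
#' satisfies the identity CI_E = 4*mu*(1-mu)*CI_W exactly.
#'
#' @param ci plain concentration index.
#' @param mu outcome mean.
#' @param a,b lower and upper bounds of the outcome (defaults 0, 1).
#' @return corrected index.
#' @export
erreygers_index <- function(ci, mu, a = 0, b = 1) {
  if (b <= a) stop("b must exceed a", call. = FALSE)
  4 * mu / (b - a) * ci
}

#' Standard error of a concentration index by convenient regression
#'
#' Slope of the weighted regression of 2*var_w(R)*(y/mu) on the fractional
#' rank equals the concentration index; its heteroskedasticity-robust (HC1)
#' standard error is the index's standard error. Degenerate outcomes
#' (constant y) return se = 0 with a flag.
#'
#' @param y outcome vector.
#' @param rank fractional rank (weighted mean 0.5).
#' @param weights positive weights; equal if NULL.
#' @return list with `se`, `p_value`, `degenerate`.
#' @export
ci_standard_error <- function(y, rank, weights = NULL) {
  n <- length(y)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  wt <- weights / sum(weights)
  mu <- sum(wt * y)
  var_r <- .wcov(rank, rank, weights)
  if (var_r <= 0) stop("degenerate rank variance", call. = FALSE)
  if (stats::var(y) == 0)
    return(list(se = 0, p_value = NA_real_, degenerate = TRUE))
  lhs <- 2 * var_r * y / mu
  X <- cbind(1, rank)
  XtWX <- crossprod(X, X * wt)
  beta <- solve(XtWX, crossprod(X, lhs * wt))
  e <- lhs - X %*% beta
  n_eff <- sum(weights)^2 / sum(weights^2)
  meat <- crossprod(X, X * (wt^2 * as.numeric(e)^2))
  V <- solve(XtWX, t(solve(XtWX, t(meat)))) * n_eff / (n_eff - 2)
  se <- sqrt(V[2, 2])
  z <- beta[2] / se
  list(se = se, p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

.stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) return("***")
  if (p < 0.01) return("**")
  if (p < 0.05) return("*")
  ""
}

#' Concentration index of an outcome against the living-standards rank
#'
#' The plain index is twice the weighted covariance between the outcome and
#' the fractional rank, divided by the outcome mean; negative values indicate
#' concentration among the poor (pro-poor), positive among the rich. For
#' binary outcomes the Wagstaff-normalized and Erreygers-corrected versions
#' are attached; for continuous outcomes (e.g. benefit amounts) only the
#' plain index is meaningful and the corrections are NA.
#'
#' @param y outcome vector (binary 0/1 or non-negative continuous).
#' @param rank fractional rank from [fractional_rank()].
#' @param weights positive weights; equal if NULL.
#' @param outcome_name label carried into reports.
#' @param se compute the robust standard error (default TRUE).
#' @return object of class `ci_estimate` with fields `index_plain`,
#'   `index_wagstaff`, `index_erreygers`, `mean_outcome`, `bounds`, `se`,
#'   `p_value`, `stars`, `n_eff`, `outcome_name`.
#' @export
concentration_index <- function(y, rank, weights = NULL, outcome_name = "y",
                                se = TRUE) {
  n <- length(y)
  stopifnot(length(rank) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  wt <- weights / sum(weights)
  mu <- sum(wt * y)
  if (mu == 0)
    stop("outcome mean is 0: concentration index undefined (no utilization)",
         call. = FALSE)
  binary <- all(y %in% c(0, 1))
  ci <- 2 / mu * .wcov(y, rank, weights)
  if (binary) {
    if (mu == 1) {
      ciw <- NA_real_  # normalization undefined at mu = 1
    } else {
      ciw <- wagstaff_normalize(ci, mu)
    }
    cie <- erreygers_index(ci, mu, 0, 1)
  } else {
    ciw <- NA_real_
    cie <- NA_real_
  }
  sef <- if (se) ci_standard_error(y, rank, weights)
         else list(se = NA_real_, p_value = NA_real_, degenerate = FALSE)
  structure(list(index_plain = ci, index_wagstaff = ciw, index_erreygers = cie,
                 mean_outcome = mu, bounds = if (binary) c(0, 1) else
                   range(y),
                 se = sef$se, p_value = sef$p_value,
                 stars = .stars(sef$p_value),
                 n_eff = sum(weights)^2 / sum(weights^2),
                 binary = binary, degenerate = isTRUE(sef$degenerate),
                 outcome_name = outcome_name),
            class = "ci_estimate")
}

#' @export
print.ci_estimate <- function(x, ...) {
  cat(sprintf("<ci_estimate> %s: CI = %.4f%s (se %.4f), mu = %.4f\n",
              x$outcome_name, x$index_plain, x$stars, x$se, x$mean_outcome))
  if (x$binary)
    cat(sprintf("  Wagstaff %.4f | Erreygers %.4f\n",
                x$index_wagstaff, x$index_erreygers))
  invisible(x)
}

#' Quintile utilization table with concentration indices
#'
#' Weighted mean use per consumption quintile for each outcome, with the
#' outcome's concentration index estimates alongside — the standard
#' "quintile distribution, inequality and inequity" report layout.
#'
#' @param ranked a [rank_dataset()] result.
#' @param outcomes character vector of outcome column names in the individual
#'   table (defaults to the four service indicators plus the two totals, which
#'   are added if absent).
#' @return data.frame with one row per outcome: `Q1`..`Q5` weighted means,
#'   `mean`, `ci_plain`, `ci_wagstaff`, `ci_erreygers`, `se`, `stars`.
#' @export
quintile_use_table <- function(ranked, outcomes = NULL) {
  stopifnot(inherits(ranked, "ranked_dataset"))
  ind <- ranked$individuals
  if (is.null(ind$total_outpatient)) {
    tot <- build_total_use(ranked)
    ind$total_outpatient <- tot$total_outpatient
    ind$total_inpatient <- tot$total_inpatient
  }
  if (is.null(outcomes))
    outcomes <- c(.use_cols, "total_outpatient", "total_inpatient")
  rows <- lapply(outcomes, function(oc) {
    y <- ind[[oc]]
    if (is.null(y)) stop(sprintf("outcome '%s' not found", oc), call. = FALSE)
    qm <- vapply(1:5, function(q) {
      sel <- ind$quintile == q
      if (!any(sel)) return(NA_real_)
      weighted_mean(y[sel], ind$weight[sel])
    }, numeric(1))
    est <- concentration_index(y, ind$frac_rank, ind$weight, outcome_name = oc)
    data.frame(outcome = oc, Q1 = qm[1], Q2 = qm[2], Q3 = qm[3], Q4 = qm[4],
               Q5 = qm[5], mean = est$mean_outcome,
               ci_plain = est$index_plain, ci_wagstaff = est$index_wagstaff,
               ci_erreygers = est$index_erreygers, se = est$se,
               stars = est$stars, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
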