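#' Need-predicted utilization (indirect standardization, step 1)
#'
#' Predicts each person's utilization from the *need* factors at their actual
#' values with every non-need factor held at its weighted mean, using the
#' fitted model's linear approximation. Because the linearization is
#' mean-preserving, the prediction's weighted mean equals the model mean when
#' need factors are also at their means.
#'
#' @param fit a `pe_fit` from [fit_partial_effects()].
#' @param X the covariate matrix the model was fitted on.
#' @param need logical per column of `X`: TRUE for need factors.
#' @param weights positive weights; equal if NULL.
#' @return numeric vector of need-predicted use.
#' @export
need_predict <- function(fit, X, need, weights = NULL) {
  stopifnot(inherits(fit, "pe_fit"), ncol(X) == length(fit$coef),
            length(need) == ncol(X))
  if (!any(need)) return(rep(fit$mu, nrow(X)))
  Xn <- X
  for (j in which(!need)) Xn[, j] <- fit$xbar[j]
  as.numeric(fit$intercept + Xn %*% fit$coef)
}

#' Need-standardized utilization (indirect standardization, step 2)
#'
#' standardized_i = y_i - need_predicted_i + mean(full prediction); the
#' re-centering guarantees the standardized variable keeps the actual
#' weighted mean. Values may leave [0, 1]; they are deliberately *not*
#' clipped, since clipping would break both mean preservation and the
#' additive identity with the decomposition.
#'
#' @param y actual binary use.
#' @param need_predicted from [need_predict()].
#' @param fit the `pe_fit` the prediction came from.
#' @return numeric vector with weighted mean equal to that of `y`.
#' @export
standardize_use <- function(y, need_predicted, fit) {
  y - need_predicted + fit$mu
}

#' Horizontal inequity of a utilization outcome
#'
#' Fits the utilization model (need + non-need + consumption), indirectly
#' standardizes use for need, and measures the concentration index of the
#' standardized variable: the inequality remaining after legitimate
#' (need-driven) differences are removed. Positive HI = pro-rich inequity.
#' Two routes are computed and compared: the CI of the standardized variable
#' and CI minus the summed need contributions of the decomposition; with the
#' linear approximation they agree to machine precision. The Wagstaff
#' normalization (dividing by 1 - mu of the actual binary use) is applied as
#' for the CI.
#'
#' @param ranked a [rank_dataset()] result.
#' @param outcome outcome column or `"total_outpatient"` /
#'   `"total_inpatient"`.
#' @param method `"probit"` (default) or `"lpm"`.
#' @param use_weights use sampling weights (default TRUE).
#' @return object of class `hi_estimate`: list with `ci` (ci_estimate of
#'   actual use), `hi_plain`, `hi_wagstaff`, `c_need_predicted`,
#'   `route_difference`, `mean_actual`, `mean_standardized`, `standardized`,
#'   `decomposition`.
#' @export
horizontal_inequity <- function(ranked, outcome = "total_outpatient",
                                method = c("probit", "lpm"),
                                use_weights = TRUE) {
  stopifnot(inherits(ranked, "ranked_dataset"))
  ind <- ranked$individuals
  y <- if (outcome %in% c("total_outpatient", "total_inpatient"))
    build_total_use(ranked)[[outcome]] else ind[[outcome]]
  if (is.null(y)) stop(sprintf("outcome '%s' not found", outcome),
                       call. = FALSE)
  w <- if (use_weights) ind$weight else rep(1, nrow(ind))
  d <- build_design(ranked)
  dec <- decompose_ci(y, d$X, w, ind$frac_rank, group = d$group,
                      need = d$need, method = method)
  fit <- attr(dec, "fit")
  yhat_need <- need_predict(fit, d$X, d$need, w)
  ystd <- standardize_use(y, yhat_need, fit)
  mu <- fit$mu
  hi_plain <- 2 / mu * .wcov(ystd, ind$frac_rank, w)
  hi_route2 <- attr(dec, "ci_plain") - sum(dec$contribution[dec$need])
  cn <- 2 / mu * .wcov(yhat_need, ind$frac_rank, w)
  sef <- ci_standard_error(ystd, ind$frac_rank, w)
  structure(list(
    outcome = outcome,
    ci = concentration_index(y, ind$frac_rank, w, outcome_name = outcome),
    hi_plain = hi_plain,
    hi_wagstaff = wagstaff_normalize(hi_plain, mu),
    se = sef$se, p_value = sef$p_value, stars = .stars(sef$p_value),
    c_need_predicted = cn,
    route_difference = hi_plain - hi_route2,
    mean_actual = mu,
    mean_standardized = weighted_mean(ystd, w),
    standardized = ystd,
    decomposition = dec), class = "hi_estimate")
}

#' @export
print.hi_estimate <- function(x, ...) {
  cat(sprintf("<hi_estimate> %s\n", x$outcome))
  cat(sprintf("  CI (Wagstaff) = %.4f | C_need_predicted = %.4f | HI (Wagstaff) = %.4f%s\n",
              x$ci$index_wagstaff, x$c_need_predicted / (1 - x$mean_actual),
              x$hi_wagstaff, x$stars))
  invisible(x)
}

#' Inequity summary across outcomes
#'
#' Table-4-style report: quintile means, CI, concentration of need-predicted
#' use and HI for each outcome. CIs and HIs are Wagstaff normalized.
#'
#' @param ranked a [rank_dataset()] result.
#' @param outcomes outcome columns (default the four services + two totals).
#' @param method passed through.
#' @return data.frame, one row per outcome.
#' @export
inequity_table <- function(ranked, outcomes = NULL,
                           method = c("probit", "lpm")) {
  if (is.null(outcomes))
    outcomes <- c(.use_cols, "total_outpatient", "total_inpatient")
  qt <- quintile_use_table(ranked, outcomes)
  his <- lapply(outcomes, function(oc)
    horizontal_inequity(ranked, oc, method = method))
  qt$c_need_predicted <- vapply(his, function(h)
    wagstaff_normalize(h$c_need_predicted, h$mean_actual), numeric(1))
  qt$hi_wagstaff <- vapply(his, function(h) h$hi_wagstaff, numeric(1))
  qt$hi_stars <- vapply(his, function(h) h$stars, character(1))
  qt
}
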