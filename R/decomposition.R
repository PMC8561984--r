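#' Combined any-use indicators per level of care
#'
#' Total outpatient use is 1 if the person used a public or a private
#' outpatient service (1-month recall); total inpatient use likewise over
#' the 12-month recall. Logical OR, so no double counting.
#'
#' @param dataset a `survey_dataset` (or `ranked_dataset`).
#' @return data.frame with binary `total_outpatient` and `total_inpatient`.
#' @export
build_total_use <- function(dataset) {
  ind <- dataset$individuals
  data.frame(
    total_outpatient = as.integer(ind$use_out_public | ind$use_out_private),
    total_inpatient = as.integer(ind$use_inp_public | ind$use_inp_private))
}

# Default covariate sets for the utilization model.
.need_vars <- c("age_years", "gender", "disability", "ncd")
.non_need_vars <- c("urban", "governorate", "family_size", "educ_head",
                    "duration_cat", "knowledge", "employed_head")

#' Design matrix for the utilization model
#'
#' Encodes the survey covariates: age in years (scalar), male dummy,
#' disability and chronic-disease indicators (need set); urban, governorate
#' dummies (reference Cairo when present, else the first level), household
#' size, education of the head as dummies versus the lowest level, duration
#' of asylum as an ordinal score 1-4, service-availability knowledge and
#' head's employment (non-need set); and the consumption fractional rank.
#'
#' @param ranked a [rank_dataset()] result.
#' @param need_vars,non_need_vars variable names (defaults above).
#' @param consumption_var column used as the living-standards regressor
#'   (default `frac_rank`).
#' @return list with `X` (numeric matrix, no intercept), `group` (variable
#'   group per column) and `need` (logical per column).
#' @export
build_design <- function(ranked, need_vars = .need_vars,
                         non_need_vars = .non_need_vars,
                         consumption_var = "frac_rank") {
  ind <- ranked$individuals
  cols <- list(); grp <- character(); need <- logical()
  add <- function(values, name, group, is_need) {
    cols[[name]] <<- as.numeric(values)
    grp <<- c(grp, group); need <<- c(need, is_need)
  }
  encode <- function(var, is_need) {
    switch(var,
      gender = add(ind$gender == "male", "male", "gender", is_need),
      governorate = {
        levs <- sort(unique(ind$governorate))
        ref <- if ("Cairo" %in% levs) "Cairo" else levs[1]
        for (l in setdiff(levs, ref))
          add(ind$governorate == l, paste0("gov_", gsub("\\s+", "_", l)),
              "governorate", is_need)
      },
      educ_head = {
        for (l in intersect(.educ_levels[-1], unique(ind$educ_head)))
          add(ind$educ_head == l, paste0("educ_", l), "educ_head", is_need)
      },
      duration_cat = add(match(ind$duration_cat, .duration_levels),
                         "duration", "duration_cat", is_need),
      {
        if (is.null(ind[[var]]))
          stop(sprintf("covariate '%s' not found", var), call. = FALSE)
        add(ind[[var]], var, var, is_need)
      })
  }
  for (v in need_vars) encode(v, TRUE)
  for (v in non_need_vars) encode(v, FALSE)
  if (!is.null(consumption_var)) {
    if (is.null(ind[[consumption_var]]))
      stop(sprintf("consumption covariate '%s' not found", consumption_var),
           call. = FALSE)
    add(ind[[consumption_var]], "consumption", "consumption", FALSE)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, group = grp, need = need)
}

#' Probit fit with partial effects at means (LPM fallback)
#'
#' Fits a weighted probit of the binary outcome on the covariates and
#' linearizes it: the working coefficients are the marginal effects at the
#' weighted covariate means, beta_m = phi(xbar' theta) * theta, with the
#' intercept chosen so the linear approximation reproduces the weighted
#' outcome mean at the means. When the probit fails to converge or the
#' outcome is separable, a weighted linear probability model is used instead
#' (flagged). Rank-deficient designs are an error naming the collinear
#' columns.
#'
#' @param y binary outcome.
#' @param X numeric covariate matrix (no intercept column).
#' @param weights positive weights; equal if NULL.
#' @param method `"probit"` (default) or `"lpm"`.
#' @return object of class `pe_fit`: list with `coef` (named marginal
#'   effects), `intercept`, `mu`, `xbar` (weighted covariate means),
#'   `method`, `converged`, `linear_pred`, `residuals`.
#' @export
fit_partial_effects <- function(y, X, weights = NULL,
                                method = c("probit", "lpm")) {
  method <- match.arg(method)
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  wt <- weights / sum(weights)
  mu <- sum(wt * y)
  if (is.null(X) || ncol(X) == 0) {
    return(structure(list(coef = numeric(0), intercept = mu, mu = mu,
                          xbar = numeric(0), method = method, converged = TRUE,
                          linear_pred = rep(mu, n), residuals = y - mu),
                     class = "pe_fit"))
  }
  qr_x <- qr(cbind(1, X) * sqrt(wt))
  if (qr_x$rank < ncol(X) + 1) {
    bad <- colnames(cbind(`(Intercept)` = 1, X))[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  xbar <- colSums(X * wt)
  used <- method
  beta_m <- NULL
  if (method == "probit") {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, X), y, weights = weights,
                                      family = stats::quasibinomial("probit"))),
      error = function(e) NULL)
    separated <- !is.null(fit) &&
      (any(abs(fit$coefficients[-1]) > 20) || !fit$converged ||
         all(abs(fit$fitted.values - y) < 1e-6))
    if (is.null(fit) || separated) {
      warning("probit failed to converge or separation detected; ",
              "falling back to a linear probability model", call. = FALSE)
      used <- "lpm"
    } else {
      theta <- fit$coefficients
      dens <- stats::dnorm(sum(c(1, xbar) * theta))
      beta_m <- dens * theta[-1]
    }
  }
  if (used == "lpm") {
    XtWX <- crossprod(cbind(1, X), cbind(1, X) * wt)
    b <- solve(XtWX, crossprod(cbind(1, X), y * wt))
    beta_m <- as.numeric(b[-1])
  }
  names(beta_m) <- colnames(X)
  intercept <- mu - sum(beta_m * xbar)   # mean-preserving linearization
  lp <- as.numeric(intercept + X %*% beta_m)
  structure(list(coef = beta_m, intercept = intercept, mu = mu, xbar = xbar,
                 method = used, converged = TRUE, linear_pred = lp,
                 residuals = y - lp),
            class = "pe_fit")
}

#' Decompose a concentration index into covariate contributions
#'
#' Writes the outcome's concentration index as the sum over covariates of
#' elasticity (beta_m_j * xbar_j / mu) times the covariate's own
#' concentration index, plus a residual (the generalized concentration index
#' of the linearization error over mu). Contributions are computed on the
#' plain-index scale (percentage contributions are scale-free); the table
#' also carries the Wagstaff and Erreygers versions of the total index.
#'
#' @param y binary outcome.
#' @param X covariate matrix from [build_design()] (or any numeric matrix).
#' @param weights positive weights; equal if NULL.
#' @param rank fractional rank vector.
#' @param group optional covariate-group labels per column.
#' @param need optional logical per column flagging need factors.
#' @param method passed to [fit_partial_effects()].
#' @return object of class `decomposition_table`: data.frame with one row per
#'   covariate (`term`, `group`, `need`, `elasticity`, `covariate_ci`,
#'   `contribution`, `pct_contribution`) and attributes `ci_plain`,
#'   `ci_wagstaff`, `ci_erreygers`, `mu`, `residual` (CI minus the
#'   contribution sum), `residual_gc` (GC of residuals / mu), `fit`.
#' @export
decompose_ci <- function(y, X, weights = NULL, rank, group = NULL,
                         need = NULL, method = c("probit", "lpm")) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  fit <- fit_partial_effects(y, X, weights, method = method)
  mu <- fit$mu
  if (mu == 0) stop("outcome mean is 0: decomposition undefined", call. = FALSE)
  est <- concentration_index(y, rank, weights, se = FALSE)
  ci <- est$index_plain
  p <- ncol(X)
  if (is.null(group)) group <- colnames(X)
  if (is.null(need)) need <- rep(FALSE, p)
  contr <- vapply(seq_len(p), function(j)
    2 * fit$coef[j] * .wcov(X[, j], rank, weights) / mu, numeric(1))
  elas <- fit$coef * fit$xbar / mu
  cov_ci <- ifelse(abs(fit$xbar) > 0,
                   vapply(seq_len(p), function(j)
                     2 * .wcov(X[, j], rank, weights) / fit$xbar[j],
                     numeric(1)),
                   NA_real_)
  tab <- data.frame(term = colnames(X), group = group, need = need,
                    elasticity = as.numeric(elas),
                    covariate_ci = as.numeric(cov_ci),
                    contribution = contr,
                    pct_contribution = contr / ci,
                    stringsAsFactors = FALSE, row.names = NULL)
  residual <- ci - sum(contr)
  residual_gc <- 2 * .wcov(fit$residuals, rank, weights) / mu
  structure(tab, class = c("decomposition_table", "data.frame"),
            ci_plain = ci,
            ci_wagstaff = if (est$binary && mu < 1)
              wagstaff_normalize(ci, mu) else NA_real_,
            ci_erreygers = if (est$binary)
              erreygers_index(ci, mu) else NA_real_,
            mu = mu, residual = residual, residual_gc = residual_gc,
            fit = fit)
}

#' Decompose utilization inequality for a survey outcome
#'
#' Convenience wrapper: builds the standard design, constructs the combined
#' any-use outcomes when asked for, and runs [decompose_ci()].
#'
#' @param ranked a [rank_dataset()] result.
#' @param outcome outcome column, or `"total_outpatient"` /
#'   `"total_inpatient"` (constructed on the fly).
#' @param method `"probit"` (default) or `"lpm"`.
#' @param use_weights use the sampling weights (default TRUE).
#' @return a `decomposition_table`.
#' @export
decompose_use <- function(ranked, outcome = "total_outpatient",
                          method = c("probit", "lpm"), use_weights = TRUE) {
  stopifnot(inherits(ranked, "ranked_dataset"))
  ind <- ranked$individuals
  y <- if (outcome %in% c("total_outpatient", "total_inpatient"))
    build_total_use(ranked)[[outcome]] else ind[[outcome]]
  if (is.null(y)) stop(sprintf("outcome '%s' not found", outcome),
                       call. = FALSE)
  d <- build_design(ranked)
  w <- if (use_weights) ind$weight else rep(1, nrow(ind))
  decompose_ci(y, d$X, w, ind$frac_rank, group = d$group, need = d$need,
               method = method)
}

#' Aggregate a decomposition table by covariate group
#'
#' Sums contributions within covariate groups (e.g. all governorate dummies),
#' which is exact because the decomposition is additive.
#'
#' @param tab a `decomposition_table`.
#' @return data.frame with one row per group: `group`, `need`,
#'   `contribution`, `pct_contribution`.
#' @export
group_contributions <- function(tab) {
  stopifnot(inherits(tab, "decomposition_table"))
  agg <- stats::aggregate(contribution ~ group + need, data = tab, FUN = sum)
  agg$pct_contribution <- agg$contribution / attr(tab, "ci_plain")
  agg[order(-agg$need, agg$group), c("group", "need", "contribution",
                                     "pct_contribution")]
}

#' @export
print.decomposition_table <- function(x, ...) {
  cat(sprintf(
    "<decomposition_table> CI = %.4f (Wagstaff %.4f, Erreygers %.4f), mu = %.4f\n",
    attr(x, "ci_plain"), attr(x, "ci_wagstaff"), attr(x, "ci_erreygers"),
    attr(x, "mu")))
  cat(sprintf("  residual = %.6f (GC route %.6f), model = %s\n",
              attr(x, "residual"), attr(x, "residual_gc"),
              attr(x, "fit")$method))
  print.data.frame(x, digits = 4)
  invisible(x)
}
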