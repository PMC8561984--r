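#' Adult-equivalent consumption
#'
#' Scales household consumption to an adult-equivalent value,
#' `consumption / family_size^theta`, to damp household economies of scale.
#' The default exponent 0.56 comes from multi-country household-survey
#' estimates of the equivalence scale.
#'
#' @param consumption_total household consumption (currency/month, >= 0).
#' @param family_size integer >= 1.
#' @param theta equivalence exponent in (0, 1]; `theta = 1` gives per-capita
#'   consumption.
#' @return equivalized consumption, same length as the inputs.
#' @export
equivalize <- function(consumption_total, family_size, theta = 0.56) {
  if (any(family_size < 1)) stop("family_size must be >= 1", call. = FALSE)
  if (any(consumption_total < 0))
    stop("consumption_total must be >= 0", call. = FALSE)
  if (!(theta > 0 && theta <= 1)) stop("theta must be in (0,1]", call. = FALSE)
  consumption_total / family_size^theta
}

#' Weighted fractional rank
#'
#' Position of each observation in the weighted living-standards distribution:
#' after sorting ascending, rank_i = (cumulative weight before i + w_i/2) /
#' total weight. Ties (equal values) are pooled: all members of a tied block
#' share the block's midpoint rank, which keeps the weighted mean rank at
#' exactly 0.5 and preserves the attainable bounds of rank-based indices.
#'
#' @param values numeric vector (the ranking variable, e.g. equivalized
#'   consumption).
#' @param weights positive weights; equal weights if NULL.
#' @return vector of fractional ranks in (0, 1), weighted mean exactly 0.5.
#' @export
fractional_rank <- function(values, weights = NULL) {
  n <- length(values)
  if (n == 0) stop("empty input", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("length mismatch", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  ord <- order(values)
  w <- weights[ord] / sum(weights)
  v <- values[ord]
  cum_before <- cumsum(w) - w
  # pooled midpoint rank per tied block
  block <- cumsum(!duplicated(v))
  block_w <- tapply(w, block, sum)
  block_start <- tapply(cum_before, block, min)
  r_sorted <- as.numeric(block_start[block] + block_w[block] / 2)
  r <- numeric(n)
  r[ord] <- r_sorted
  r
}

#' Quintile assignment on the weighted distribution
#'
#' Assigns quintile q = smallest q with cumulative-position <= q/5, using each
#' observation's *individual* midpoint position in stable sort order (ties
#' broken by input order), so that weighted quintile shares are 20% each up to
#' the granularity of a single weight even when values tie.
#'
#' @param values ranking variable.
#' @param weights positive weights; equal if NULL.
#' @return integer vector of quintiles 1..5.
#' @export
assign_quintiles <- function(values, weights = NULL) {
  n <- length(values)
  if (n == 0) stop("empty input", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  ord <- order(values)            # stable for ties
  w <- weights[ord] / sum(weights)
  pos_sorted <- cumsum(w) - w / 2 # individual midpoint position
  q_sorted <- pmin(5L, as.integer(ceiling(pos_sorted * 5 - 1e-12)))
  q_sorted <- pmax(1L, q_sorted)
  q <- integer(n)
  q[ord] <- q_sorted
  q
}

#' Rank a survey dataset by equivalized consumption
#'
#' The ranking backbone for every index: equivalizes household consumption,
#' attaches it to each member (all members share the household value, as in
#' the source survey), and computes person-level weighted fractional ranks and
#' quintiles with individuals carrying their household weight.
#'
#' @param dataset a [survey_dataset()].
#' @param theta equivalence exponent (default 0.56).
#' @return object of class `ranked_dataset`: the dataset with the individual
#'   table augmented by `eq_consumption`, `weight`, `frac_rank`, `quintile`,
#'   plus household-level context columns used by the decomposition (urban,
#'   governorate, family_size, educ_head, employed_head, duration_cat,
#'   knowledge).
#' @export
rank_dataset <- function(dataset, theta = 0.56) {
  stopifnot(inherits(dataset, "survey_dataset"))
  hh <- dataset$households
  ind <- dataset$individuals
  if (is.null(hh$consumption_total) || is.null(hh$family_size))
    stop("ranking requires household consumption_total and family_size",
         call. = FALSE)
  hh$eq_consumption <- equivalize(hh$consumption_total, hh$family_size, theta)
  carry <- c("eq_consumption", "weight", "urban", "governorate", "family_size",
             "educ_head", "employed_head", "duration_cat", "knowledge")
  idx <- match(ind$household_id, hh$household_id)
  for (col in carry) ind[[col]] <- hh[[col]][idx]
  ind$frac_rank <- fractional_rank(ind$eq_consumption, ind$weight)
  ind$quintile <- assign_quintiles(ind$eq_consumption, ind$weight)
  out <- dataset
  out$individuals <- ind
  out$households <- hh
  out$theta <- theta
  class(out) <- c("ranked_dataset", "survey_dataset")
  out
}

#' @export
print.ranked_dataset <- function(x, ...) {
  NextMethod()
  qs <- tapply(x$individuals$weight, x$individuals$quintile, sum)
  cat("  weighted quintile shares:",
      paste(sprintf("%.3f", qs / sum(x$individuals$weight)), collapse = " "),
      "\n")
  invisible(x)
}
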