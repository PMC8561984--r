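#' Configuration for the synthetic household survey generator
#'
#' The defaults state the world the analysis pipeline is exercised in:
#' 507 households averaging 3.6 +/- 2.2 members, a log-normal equivalized
#' consumption distribution whose quintile means approximate the source
#' survey's ($40 to $182/month), chronic-disease prevalence 20.4% rising
#' with age and concentrated among the poor, disability 3.4%, and per-service
#' probit utilization models whose intercepts are calibrated (see
#' `scripts/calibrate_coefficients.R`) so the weighted use means match the
#' observed margins (public/private outpatient 0.13/0.18, public/private
#' inpatient 0.07/0.02). The consumption-rank coefficients encode the
#' observed sign structure: pro-poor public outpatient use, pro-rich private
#' outpatient use.
#'
#' @param n_households number of households (default 507).
#' @param mean_household_size,sd_household_size moments of the (shifted
#'   negative binomial) household-size distribution; defaults 3.6, 2.2.
#' @param governorate_shares named sampling shares (must sum to 1).
#' @param consumption_meanlog,consumption_sdlog log-normal parameters of
#'   equivalized consumption (USD/month).
#' @param ncd_prevalence,disability_prevalence target prevalences.
#' @param age_group_shares named shares over the five survey age groups.
#' @param male_share,urban_share,employed_share,knowledge_share Bernoulli
#'   shares of the respective indicators.
#' @param educ_shares,duration_shares named shares over the categorical
#'   levels.
#' @param ncd_model probit coefficients for chronic disease: `intercept`,
#'   `age_decade` (per 10 years), `rank` (on the population consumption
#'   rank).
#' @param utilization_coefficients per-service named vectors with elements
#'   `intercept`, `female`, `ncd`, `disability`, `age_decade`, `rank`.
#' @param oop_model per-service list(`price`, `frac_base`, `frac_slope`,
#'   `shape`, `cap`): out-of-pocket is price * Beta-distributed fraction with
#'   mean `frac_base + frac_slope * rank` (clipped), precision `shape`,
#'   bounded by price * cap.
#' @param consumption_class_shares split of household consumption into the
#'   six expenditure classes.
#' @param theta equivalence exponent used to map equivalized consumption
#'   back to the household total.
#' @param seed integer RNG seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
  n_households = 507,
  mean_household_size = 3.6, sd_household_size = 2.2,
  governorate_shares = c("6 October and Giza" = 0.285, "Cairo" = 0.206,
                         "Alexandria" = 0.116, "Qalyubia" = 0.116,
                         "Sharkia" = 0.067, "Damietta" = 0.098,
                         "Others" = 0.112),
  consumption_meanlog = 4.4285, consumption_sdlog = 0.55,
  ncd_prevalence = 0.204, disability_prevalence = 0.034,
  age_group_shares = c("0-5" = 0.095, "6-17" = 0.323, "18-34" = 0.316,
                       "35-64" = 0.247, "65+" = 0.020) / 1.001,
  male_share = 0.52, urban_share = 0.888, employed_share = 0.526,
  knowledge_share = 0.5,
  educ_shares = c(none_primary_prep = 0.689, secondary_technical = 0.192,
                  university_plus = 0.119),
  duration_shares = c("<2y" = 0.21, "2-4y" = 0.07, "4-5y" = 0.67,
                      ">5y" = 0.05),
  ncd_model = c(intercept = NA_real_, age_decade = 0.45, rank = -0.35),
  utilization_coefficients = NULL,
  oop_model = NULL,
  consumption_class_shares = c(consumption_food = 0.38,
                               consumption_nonfood = 0.22,
                               consumption_durables = 0.18,
                               consumption_housing = 0.12,
                               consumption_education = 0.05,
                               consumption_health = 0.05),
  theta = 0.56,
  seed = 1) {
  if (is.null(utilization_coefficients))
    utilization_coefficients <- .default_util_coefs()
  if (is.na(ncd_model["intercept"]))
    ncd_model["intercept"] <- .default_ncd_intercept()
  if (is.null(oop_model)) oop_model <- .default_oop_model()
  cfg <- list(n_households = n_households,
              mean_household_size = mean_household_size,
              sd_household_size = sd_household_size,
              governorate_shares = governorate_shares,
              consumption_meanlog = consumption_meanlog,
              consumption_sdlog = consumption_sdlog,
              ncd_prevalence = ncd_prevalence,
              disability_prevalence = disability_prevalence,
              age_group_shares = age_group_shares,
              male_share = male_share, urban_share = urban_share,
              employed_share = employed_share,
              knowledge_share = knowledge_share,
              educ_shares = educ_shares, duration_shares = duration_shares,
              ncd_model = ncd_model,
              utilization_coefficients = utilization_coefficients,
              oop_model = oop_model,
              consumption_class_shares = consumption_class_shares,
              theta = theta, seed = seed)
  .validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_config <- function(cfg) {
  chk_shares <- function(x, name) {
    if (abs(sum(x) - 1) > 1e-8)
      stop(sprintf("%s must sum to 1 (got %.6f)", name, sum(x)),
           call. = FALSE)
    if (any(x < 0)) stop(sprintf("%s has negative entries", name),
                         call. = FALSE)
  }
  if (cfg$n_households < 2) stop("n_households must be >= 2", call. = FALSE)
  chk_shares(cfg$governorate_shares, "governorate_shares")
  chk_shares(cfg$age_group_shares, "age_group_shares")
  chk_shares(cfg$educ_shares, "educ_shares")
  chk_shares(cfg$duration_shares, "duration_shares")
  chk_shares(cfg$consumption_class_shares, "consumption_class_shares")
  for (p in c("ncd_prevalence", "disability_prevalence", "male_share",
              "urban_share", "employed_share", "knowledge_share"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("%s must be in [0,1]", p), call. = FALSE)
  for (k in .services)
    if (!all(c("intercept", "female", "ncd", "disability", "age_decade",
               "rank") %in% names(cfg$utilization_coefficients[[k]])))
      stop(sprintf("incomplete utilization coefficients for %s", k),
           call. = FALSE)
  invisible(cfg)
}

# Intercepts calibrated by scripts/calibrate_coefficients.R (large-n
# root-finding against the target use means); slope coefficients encode the
# documented gradients (strong chronic-disease effect, female excess in
# outpatient care, pro-poor public / pro-rich private consumption gradient).
.default_util_coefs <- function() list(
  out_public  = c(intercept = -1.45827, female = 0.15, ncd = 1.00,
                  disability = 0.10, age_decade = 0.06, rank = -0.50),
  out_private = c(intercept = -1.86688, female = 0.15, ncd = 1.00,
                  disability = 0.10, age_decade = 0.06, rank = 0.80),
  inp_public  = c(intercept = -1.95356, female = 0.35, ncd = 0.60,
                  disability = 0.20, age_decade = 0.02, rank = 0.10),
  inp_private = c(intercept = -2.60200, female = 0.30, ncd = 0.50,
                  disability = 0.30, age_decade = 0.02, rank = 0.30))

.default_ncd_intercept <- function() -2.08004

.default_oop_model <- function() list(
  out_public  = list(price = 15, frac_base = 0.10, frac_slope = 0.25,
                     shape = 8, cap = 1),
  out_private = list(price = 25, frac_base = 0.60, frac_slope = 0.30,
                     shape = 8, cap = 1),
  inp_public  = list(price = 500, frac_base = 0.02, frac_slope = 0.05,
                     shape = 8, cap = 1),
  inp_private = list(price = 700, frac_base = 0.50, frac_slope = 0.30,
                     shape = 8, cap = 1))

# Draw the member-level covariates and outcomes given household context.
.simulate_members <- function(cfg, hh_id, size, rank_pop) {
  n <- sum(size)
  hh_idx <- rep(seq_along(size), size)
  ag <- sample(names(cfg$age_group_shares), n, replace = TRUE,
               prob = cfg$age_group_shares)
  lo <- c("0-5" = 0, "6-17" = 6, "18-34" = 18, "35-64" = 35, "65+" = 65)
  hi <- c("0-5" = 6, "6-17" = 18, "18-34" = 35, "35-64" = 65, "65+" = 85)
  age <- stats::runif(n, lo[ag], hi[ag])
  female <- stats::rbinom(n, 1, 1 - cfg$male_share)
  dis <- stats::rbinom(n, 1, cfg$disability_prevalence)
  r <- rank_pop[hh_idx]
  m <- cfg$ncd_model
  ncd <- stats::rbinom(n, 1, stats::pnorm(
    m["intercept"] + m["age_decade"] * age / 10 + m["rank"] * r))
  out <- data.frame(household_id = hh_id[hh_idx], age_years = age,
                    gender = ifelse(female == 1, "female", "male"),
                    disability = dis, ncd = ncd, stringsAsFactors = FALSE)
  for (k in .services) {
    b <- cfg$utilization_coefficients[[k]]
    eta <- b["intercept"] + b["female"] * female + b["ncd"] * ncd +
      b["disability"] * dis + b["age_decade"] * age / 10 + b["rank"] * r
    use <- stats::rbinom(n, 1, stats::pnorm(eta))
    om <- cfg$oop_model[[k]]
    mfrac <- pmin(pmax(om$frac_base + om$frac_slope * r, 0.01), 0.99)
    frac <- stats::rbeta(n, om$shape * mfrac, om$shape * (1 - mfrac))
    oop <- use * pmin(om$price * frac, om$price * om$cap)
    out[[paste0("use_", k)]] <- use
    out[[paste0("oop_", k)]] <- oop
  }
  out
}

#' Generate a synthetic household survey
#'
#' Draws households (size from a shifted negative binomial matching the
#' configured mean/sd with minimum size 1; equivalized consumption log-normal
#' and shared by all members, inducing the intra-household correlation the
#' estimators must tolerate), then members (age, gender, disability, chronic
#' disease rising with age and falling with consumption rank) and per-service
#' binary utilization from the probit model, with out-of-pocket amounts drawn
#' only for users and never negative. Reproducible: a fixed seed yields an
#' identical dataset.
#'
#' @param config a [synthetic_config()].
#' @return a validated [survey_dataset()].
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  nh <- cfg$n_households
  hh_id <- sprintf("hh%04d", seq_len(nh))
  size <- .draw_household_size(nh, cfg$mean_household_size,
                               cfg$sd_household_size)
  eq <- stats::rlnorm(nh, cfg$consumption_meanlog, cfg$consumption_sdlog)
  rank_pop <- stats::plnorm(eq, cfg$consumption_meanlog,
                            cfg$consumption_sdlog)
  cons_total <- eq * size^cfg$theta
  hh <- data.frame(household_id = hh_id, family_size = size,
                   stringsAsFactors = FALSE)
  for (cl in names(cfg$consumption_class_shares))
    hh[[cl]] <- cons_total * cfg$consumption_class_shares[[cl]]
  hh$urban <- stats::rbinom(nh, 1, cfg$urban_share)
  hh$governorate <- sample(names(cfg$governorate_shares), nh, replace = TRUE,
                           prob = cfg$governorate_shares)
  hh$educ_head <- sample(names(cfg$educ_shares), nh, replace = TRUE,
                         prob = cfg$educ_shares)
  hh$employed_head <- stats::rbinom(nh, 1, cfg$employed_share)
  hh$duration_cat <- sample(names(cfg$duration_shares), nh, replace = TRUE,
                            prob = cfg$duration_shares)
  hh$knowledge <- stats::rbinom(nh, 1, cfg$knowledge_share)
  hh$weight <- 1
  ind <- .simulate_members(cfg, hh_id, size, rank_pop)
  ind$person_id <- sprintf("p%05d", seq_len(nrow(ind)))
  survey_dataset(ind, hh)
}

# Shifted negative binomial: size = 1 + NB(mu, theta) with moments matched to
# the requested mean/sd (overdispersed, no zero-size households). Falls back
# to Poisson when the requested variance is at or below the mean.
.draw_household_size <- function(n, mean_size, sd_size) {
  mu <- mean_size - 1
  v <- sd_size^2
  if (v > mu + 1e-9) {
    th <- mu^2 / (v - mu)
    1L + stats::rnbinom(n, mu = mu, size = th)
  } else {
    1L + stats::rpois(n, mu)
  }
}

#' Population concentration index of the generative model
#'
#' Monte-Carlo oracle for parameter recovery: simulates `n_mc` individuals
#' directly from the configured generative model (fresh households, true
#' population consumption ranks) and returns the concentration index of the
#' requested service's utilization with its Monte-Carlo standard error.
#'
#' @param config a [synthetic_config()].
#' @param service one of `out_public`, `out_private`, `inp_public`,
#'   `inp_private`, or `total_outpatient` / `total_inpatient`.
#' @param n_mc number of simulated individuals (default 2e5).
#' @param seed RNG seed for the oracle draw (default `config$seed + 1e6`,
#'   kept distinct from the survey draw).
#' @return list with `value` (the index), `se` (MC standard error), `n_mc`.
#' @export
true_concentration_index <- function(config, service, n_mc = 2e5,
                                     seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  if (is.null(seed)) seed <- cfg$seed + 1000003L
  set.seed(seed)
  nh <- ceiling(n_mc / cfg$mean_household_size)
  size <- .draw_household_size(nh, cfg$mean_household_size,
                               cfg$sd_household_size)
  eq <- stats::rlnorm(nh, cfg$consumption_meanlog, cfg$consumption_sdlog)
  r <- stats::plnorm(eq, cfg$consumption_meanlog, cfg$consumption_sdlog)
  ind <- .simulate_members(cfg, sprintf("hh%07d", seq_len(nh)), size, r)
  y <- switch(service,
    total_outpatient = as.integer(ind$use_out_public | ind$use_out_private),
    total_inpatient = as.integer(ind$use_inp_public | ind$use_inp_private),
    {
      col <- paste0("use_", service)
      if (is.null(ind[[col]]))
        stop(sprintf("unknown service '%s'", service), call. = FALSE)
      ind[[col]]
    })
  rank_i <- r[rep(seq_along(size), size)]
  est <- concentration_index(y, rank_i, outcome_name = service)
  list(value = est$index_plain, se = est$se, n_mc = nrow(ind))
}

#' Default provider cost ledger for the synthetic world
#'
#' Only the public (subsidized) services carry provider spending; the split
#' is 28.6% outpatient / 71.4% inpatient of a configurable yearly budget,
#' with unit counts chosen so unit costs equal the generator's public
#' service prices.
#'
#' @param total_spending yearly subsidy budget (default 1e6 USD).
#' @param config a [synthetic_config()] supplying the public unit prices.
#' @return a [cost_ledger()].
#' @export
default_cost_ledger <- function(total_spending = 1e6,
                                config = synthetic_config()) {
  prices <- c(out_public = config$oop_model$out_public$price,
              inp_public = config$oop_model$inp_public$price)
  spend <- c(out_public = 0.286, inp_public = 0.714) * total_spending
  cost_ledger(data.frame(service = names(spend),
                         total_spending = as.numeric(spend),
                         total_units = as.numeric(round(spend / prices)),
                         row.names = NULL))
}
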