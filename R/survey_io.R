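#' @keywords internal
"_PACKAGE"

# Canonical column sets and categorical levels for the survey schema.
.services <- c("out_public", "out_private", "inp_public", "inp_private")
.use_cols <- paste0("use_", .services)
.oop_cols <- paste0("oop_", .services)

.age_group_levels <- c("0-5", "6-17", "18-34", "35-64", "65+")
.educ_levels <- c("none_primary_prep", "secondary_technical", "university_plus")
.duration_levels <- c("<2y", "2-4y", "4-5y", ">5y")
.consumption_classes <- c("consumption_food", "consumption_nonfood",
                          "consumption_durables", "consumption_housing",
                          "consumption_education", "consumption_health")

.individual_cols <- c("person_id", "household_id", "age_years", "gender",
                      "disability", "ncd", .use_cols, .oop_cols)
.household_cols <- c("household_id", "family_size", .consumption_classes,
                     "urban", "governorate", "educ_head", "employed_head",
                     "duration_cat", "knowledge", "weight")

#' Map age in years to the survey age group
#'
#' @param age_years numeric vector of non-negative ages.
#' @return factor with levels `0-5`, `6-17`, `18-34`, `35-64`, `65+`.
#' @export
age_group <- function(age_years) {
  stopifnot(is.numeric(age_years), all(age_years >= 0))
  cut(age_years, breaks = c(-Inf, 6, 18, 35, 65, Inf), right = FALSE,
      labels = .age_group_levels)
}

.check_binary <- function(x, name) {
  if (!all(x %in% c(0, 1)))
    stop(sprintf("column '%s' must be binary 0/1", name), call. = FALSE)
  as.integer(x)
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s file is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Construct and validate a survey dataset
#'
#' Bundles individual-level records (demographics, need factors, the four
#' binary utilization indicators and their out-of-pocket amounts) with the
#' household roster (consumption by class, socioeconomic non-need factors and
#' sampling weights). All schema invariants are enforced here: binary fields,
#' referential integrity between persons and households, family size equal to
#' the member count, non-negative money amounts, and out-of-pocket spending
#' only where the matching use indicator is positive (positive use with a
#' missing OOP amount is read as "none reported" and set to 0 with a warning).
#'
#' @param individuals data.frame with the individual schema (see
#'   [read_survey()] for column names).
#' @param households data.frame with the household schema.
#' @param currency_rate EGP per USD used when monetary columns are supplied in
#'   EGP; analysis is always in USD. Default 17.6.
#' @return an object of class `survey_dataset`: a list with elements
#'   `individuals`, `households` (validated data.frames) and `currency_rate`.
#' @export
survey_dataset <- function(individuals, households, currency_rate = 17.6) {
  individuals <- as.data.frame(individuals)
  households <- as.data.frame(households)
  .check_columns(individuals, .individual_cols, "individual")
  .check_columns(households, .household_cols, "household")

  if (anyDuplicated(individuals$person_id))
    stop("duplicate person_id in individual records", call. = FALSE)
  if (anyDuplicated(households$household_id))
    stop("duplicate household_id in household records", call. = FALSE)

  orphan <- setdiff(individuals$household_id, households$household_id)
  if (length(orphan))
    stop(sprintf("individuals reference unknown household_id(s): %s",
                 paste(utils::head(orphan, 5), collapse = ", ")), call. = FALSE)

  if (any(individuals$age_years < 0)) stop("negative age_years", call. = FALSE)
  individuals$gender <- tolower(as.character(individuals$gender))
  if (!all(individuals$gender %in% c("male", "female")))
    stop("gender must be 'male' or 'female'", call. = FALSE)
  for (col in c("disability", "ncd", .use_cols))
    individuals[[col]] <- .check_binary(individuals[[col]], col)

  for (k in .services) {
    use <- individuals[[paste0("use_", k)]]
    oop_col <- paste0("oop_", k)
    oop <- individuals[[oop_col]]
    if (anyNA(oop[use == 1])) {
      warning(sprintf("missing %s with positive use treated as 0", oop_col),
              call. = FALSE)
      oop[use == 1 & is.na(oop)] <- 0
    }
    oop[is.na(oop)] <- 0
    if (any(oop < 0)) stop(sprintf("negative %s", oop_col), call. = FALSE)
    if (any(oop > 0 & use == 0))
      stop(sprintf("%s positive while use_%s is 0", oop_col, k), call. = FALSE)
    individuals[[oop_col]] <- as.numeric(oop)
  }
  individuals$age_group <- as.character(age_group(individuals$age_years))

  households$family_size <- as.integer(households$family_size)
  if (any(households$family_size < 1))
    stop("family_size must be >= 1", call. = FALSE)
  counts <- table(individuals$household_id)
  got <- as.integer(counts[as.character(households$household_id)])
  got[is.na(got)] <- 0L
  if (any(got != households$family_size))
    stop("family_size does not match the member count for some household(s)",
         call. = FALSE)

  for (col in .consumption_classes) {
    households[[col]] <- as.numeric(households[[col]])
    if (any(households[[col]] < 0))
      stop(sprintf("negative %s", col), call. = FALSE)
  }
  households$consumption_total <-
    rowSums(households[, .consumption_classes, drop = FALSE])
  households$urban <- .check_binary(households$urban, "urban")
  households$employed_head <- .check_binary(households$employed_head,
                                            "employed_head")
  households$governorate <- as.character(households$governorate)
  households$educ_head <- as.character(households$educ_head)
  if (!all(households$educ_head %in% .educ_levels))
    stop(sprintf("educ_head levels must be among: %s",
                 paste(.educ_levels, collapse = ", ")), call. = FALSE)
  households$duration_cat <- as.character(households$duration_cat)
  if (!all(households$duration_cat %in% .duration_levels))
    stop(sprintf("duration_cat levels must be among: %s",
                 paste(.duration_levels, collapse = ", ")), call. = FALSE)
  households$knowledge <- as.numeric(households$knowledge)
  households$weight <- as.numeric(households$weight)
  if (any(!is.finite(households$weight)) || any(households$weight <= 0))
    stop("household weight must be > 0", call. = FALSE)

  structure(list(individuals = individuals, households = households,
                 currency_rate = currency_rate),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset> %d individuals in %d households\n",
              nrow(x$individuals), nrow(x$households)))
  mu <- vapply(.use_cols, function(c) mean(x$individuals[[c]]), numeric(1))
  cat("  mean use:", paste(sprintf("%s=%.3f", .services, mu), collapse = " "),
      "\n")
  invisible(x)
}

#' Read a survey from CSV files
#'
#' Expects `individuals.csv` (person_id, household_id, age_years, gender,
#' disability, ncd, use_/oop_ columns for the four services) and
#' `households.csv` (household_id, family_size, six consumption classes,
#' urban, governorate, educ_head, employed_head, duration_cat, knowledge,
#' weight). Monetary columns may be in EGP, in which case they are converted
#' to USD at `currency_rate` on load.
#'
#' @param individual_file,household_file CSV paths.
#' @param currency `"USD"` (default) or `"EGP"`.
#' @param currency_rate EGP per USD (default 17.6).
#' @return a validated [survey_dataset()].
#' @export
read_survey <- function(individual_file, household_file,
                        currency = c("USD", "EGP"), currency_rate = 17.6) {
  currency <- match.arg(currency)
  ind <- utils::read.csv(individual_file, stringsAsFactors = FALSE)
  hh <- utils::read.csv(household_file, stringsAsFactors = FALSE)
  .check_columns(ind, .individual_cols, "individual")
  .check_columns(hh, .household_cols, "household")
  if (currency == "EGP") {
    for (col in .oop_cols) ind[[col]] <- ind[[col]] / currency_rate
    for (col in .consumption_classes) hh[[col]] <- hh[[col]] / currency_rate
  }
  survey_dataset(ind, hh, currency_rate = currency_rate)
}

#' Write a survey to CSV files
#'
#' Inverse of [read_survey()]: writes `individuals.csv` and `households.csv`
#' into `dir` so that reading them back reproduces the dataset field by field.
#'
#' @param dataset a `survey_dataset`.
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_survey <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fi <- file.path(dir, "individuals.csv")
  fh <- file.path(dir, "households.csv")
  ind <- dataset$individuals[, .individual_cols]
  hh <- dataset$households[, .household_cols]
  utils::write.csv(ind, fi, row.names = FALSE, quote = FALSE)
  utils::write.csv(hh, fh, row.names = FALSE, quote = FALSE)
  invisible(c(individuals = fi, households = fh))
}

#' Read a provider cost ledger
#'
#' The ledger records, per subsidized service, the provider's total yearly
#' spending and total units delivered (visits or admissions); the ratio is the
#' unit cost used by the benefit incidence analysis. YAML schema:
#' `service: {total_spending: ..., total_units: ...}`.
#'
#' @param path YAML file path.
#' @return object of class `cost_ledger`: data.frame with columns `service`,
#'   `total_spending`, `total_units`.
#' @export
read_cost_ledger <- function(path) {
  raw <- yaml::read_yaml(path)
  cost_ledger(data.frame(
    service = names(raw),
    total_spending = vapply(raw, function(e) as.numeric(e$total_spending),
                            numeric(1)),
    total_units = vapply(raw, function(e) as.numeric(e$total_units),
                         numeric(1)),
    row.names = NULL))
}

#' Construct a cost ledger
#'
#' @param df data.frame with columns `service`, `total_spending`,
#'   `total_units`.
#' @return validated `cost_ledger`.
#' @export
cost_ledger <- function(df) {
  df <- as.data.frame(df)
  .check_columns(df, c("service", "total_spending", "total_units"), "ledger")
  if (any(df$total_spending < 0)) stop("negative total_spending", call. = FALSE)
  if (any(df$total_spending > 0 & df$total_units <= 0))
    stop("total_units must be > 0 for any service with positive spending",
         call. = FALSE)
  structure(df, class = c("cost_ledger", "data.frame"))
}

#' Write a cost ledger to YAML
#' @param ledger a `cost_ledger`.
#' @param path output path.
#' @export
write_cost_ledger <- function(ledger, path) {
  out <- lapply(seq_len(nrow(ledger)), function(i)
    list(total_spending = ledger$total_spending[i],
         total_units = ledger$total_units[i]))
  names(out) <- ledger$service
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a governorate population map
#' @param path YAML file mapping governorate name to population count.
#' @return named numeric vector.
#' @export
read_population <- function(path) {
  unlist(yaml::read_yaml(path))
}

#' Post-stratification weights from governorate populations
#'
#' Re-weights households so the weighted governorate distribution matches the
#' reference population: weight = (population share) / (sample share), then
#' rescaled so weights average 1 (sum to the number of households).
#' Individuals inherit their household's weight (the survey samples
#' households).
#'
#' @param dataset a `survey_dataset`.
#' @param population_by_stratum named vector, governorate -> population count.
#' @return the dataset with `weight` replaced in the household table.
#' @export
build_weights <- function(dataset, population_by_stratum) {
  stopifnot(inherits(dataset, "survey_dataset"))
  hh <- dataset$households
  strata <- unique(hh$governorate)
  missing <- setdiff(strata, names(population_by_stratum))
  if (length(missing))
    stop(sprintf("no population figure for stratum/strata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  unsampled <- setdiff(names(population_by_stratum), strata)
  if (length(unsampled) &&
      any(population_by_stratum[unsampled] > 0))
    warning(sprintf(
      "stratum with population but no sampled households: %s (weight undefined)",
      paste(unsampled, collapse = ", ")), call. = FALSE)
  pop <- population_by_stratum[strata]
  pop_share <- pop / sum(pop)
  samp_share <- as.numeric(table(hh$governorate)[strata]) / nrow(hh)
  w <- (pop_share / samp_share)[match(hh$governorate, strata)]
  w <- as.numeric(w) * nrow(hh) / sum(w)
  dataset$households$weight <- w
  dataset
}

#' Minimum sample size for estimating a proportion
#'
#' n = z^2 p(1-p) / d^2 with half-width d expressed as *relative* precision,
#' d = rel_precision * p. The raw value is rounded half-down: values within
#' 0.5 above an integer drop to it, otherwise the ceiling is taken (so
#' 384.16 -> 384).
#'
#' @param p anticipated proportion, in (0,1).
#' @param rel_precision relative half-width of the confidence interval (> 0).
#' @param alpha significance level, in (0,1).
#' @return integer sample size, at least 1.
#' @export
required_sample_size <- function(p, rel_precision, alpha = 0.05) {
  if (!(p > 0 && p < 1)) stop("p must be in (0,1)", call. = FALSE)
  if (!(rel_precision > 0)) stop("rel_precision must be > 0", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  d <- rel_precision * p
  raw <- z^2 * p * (1 - p) / d^2
  n <- if (raw - floor(raw) <= 0.5) floor(raw) else ceiling(raw)
  max(1L, as.integer(n))
}

#' Weighted mean
#' @param x numeric vector.
#' @param w weights (equal if NULL).
#' @return scalar.
#' @export
weighted_mean <- function(x, w = NULL) {
  if (is.null(w)) return(mean(x))
  sum(x * w) / sum(w)
}

# Weighted covariance with the population convention (weights normalized to 1).
.wcov <- function(x, y, w) {
  wt <- w / sum(w)
  sum(wt * (x - sum(wt * x)) * (y - sum(wt * y)))
}
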