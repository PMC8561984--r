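# Fixture builders and independent oracles shared across the suite.

# O(n^2) pairwise (Gini-covariance) oracle for the concentration index:
# CI = (1/mu) * sum_i sum_j wt_i wt_j (y_i - y_j)(R_i - R_j), an independent
# route that never touches the package's covariance code path.
ci_oracle <- function(y, rank, w = rep(1, length(y))) {
  wt <- w / sum(w)
  mu <- sum(wt * y)
  acc <- 0
  n <- length(y)
  for (i in seq_len(n))
    for (j in seq_len(n))
      acc <- acc + wt[i] * wt[j] * (y[i] - y[j]) * (rank[i] - rank[j])
  acc / mu
}

# Minimal valid 2-household / 5-individual survey.
tiny_individuals <- function() {
  data.frame(
    person_id = paste0("p", 1:5),
    household_id = c("h1", "h1", "h1", "h2", "h2"),
    age_years = c(34, 6, 2, 70, 40),
    gender = c("male", "female", "male", "female", "male"),
    disability = c(0, 0, 0, 1, 0),
    ncd = c(0, 0, 0, 1, 1),
    use_out_public = c(1, 0, 0, 1, 0),
    use_out_private = c(0, 0, 1, 0, 1),
    use_inp_public = c(0, 0, 0, 1, 0),
    use_inp_private = c(0, 0, 0, 0, 0),
    oop_out_public = c(2.5, 0, 0, 1, 0),
    oop_out_private = c(0, 0, 12, 0, 20),
    oop_inp_public = c(0, 0, 0, 30, 0),
    oop_inp_private = c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

tiny_households <- function() {
  data.frame(
    household_id = c("h1", "h2"),
    family_size = c(3, 2),
    consumption_food = c(120, 300),
    consumption_nonfood = c(60, 150),
    consumption_durables = c(50, 120),
    consumption_housing = c(40, 90),
    consumption_education = c(10, 30),
    consumption_health = c(20, 60),
    urban = c(1, 0),
    governorate = c("Cairo", "Alexandria"),
    educ_head = c("none_primary_prep", "university_plus"),
    employed_head = c(1, 0),
    duration_cat = c("4-5y", "<2y"),
    knowledge = c(1, 0),
    weight = c(1, 1.4),
    stringsAsFactors = FALSE)
}

tiny_survey <- function() survey_dataset(tiny_individuals(), tiny_households())

# A ranked dataset from the default synthetic world (cached per session).
default_ranked <- local({
  cache <- NULL
  function(seed = 1, n_households = 507) {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = seed, n_households = n_households)
      cache <<- rank_dataset(generate_survey(cfg))
    }
    cache
  }
})

# Replicate each row of a ranked toy input according to integer weights.
replicate_rows <- function(values, weights) rep(values, times = weights)
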