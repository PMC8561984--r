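test_that("read/write round trip preserves the dataset field for field", {
  ds <- tiny_survey()
  expect_equal(nrow(ds$individuals), 5)
  expect_equal(nrow(ds$households), 2)
  dir <- withr::local_tempdir()
  write_survey(ds, dir)
  ds2 <- read_survey(file.path(dir, "individuals.csv"),
                     file.path(dir, "households.csv"))
  expect_equal(ds2$individuals[, names(tiny_individuals())],
               ds$individuals[, names(tiny_individuals())])
  expect_equal(ds2$households[, names(tiny_households())],
               ds$households[, names(tiny_households())])
})

test_that("schema and integrity violations are rejected with named errors", {
  ind <- tiny_individuals(); hh <- tiny_households()
  expect_error(survey_dataset(ind[, -3], hh), "age_years")
  bad <- ind; bad$household_id[4] <- "h9"
  expect_error(survey_dataset(bad, hh), "unknown household_id")
  bad <- ind; bad$use_out_public[1] <- 2
  expect_error(survey_dataset(bad, hh), "binary")
  bad <- ind; bad$oop_inp_private[1] <- 5   # OOP without use
  expect_error(survey_dataset(bad, hh), "oop_inp_private")
  bad <- hh; bad$family_size[1] <- 4
  expect_error(survey_dataset(ind, bad), "family_size")
  bad <- hh; bad$weight[2] <- 0
  expect_error(survey_dataset(ind, bad), "weight")
})

test_that("missing OOP with positive use becomes 0 with a warning", {
  ind <- tiny_individuals()
  ind$oop_out_public[1] <- NA
  expect_warning(ds <- survey_dataset(ind, tiny_households()),
                 "treated as 0")
  expect_equal(ds$individuals$oop_out_public[1], 0)
})

test_that("age groups are derived consistently from age in years", {
  expect_equal(as.character(age_group(c(0, 5.9, 6, 17.5, 18, 34.9, 35, 64, 65, 90))),
               c("0-5", "0-5", "6-17", "6-17", "18-34", "18-34",
                 "35-64", "35-64", "65+", "65+"))
})

test_that("EGP inputs are converted to USD on load", {
  ds <- tiny_survey()
  dir <- withr::local_tempdir()
  write_survey(ds, dir)
  egp <- read_survey(file.path(dir, "individuals.csv"),
                     file.path(dir, "households.csv"), currency = "EGP",
                     currency_rate = 17.6)
  expect_equal(egp$households$consumption_total,
               ds$households$consumption_total / 17.6)
  expect_equal(egp$individuals$oop_out_private,
               ds$individuals$oop_out_private / 17.6)
})

test_that("build_weights matches population shares and normalizes to mean 1", {
  # 4 households in 2 strata sampled 50/50, population 75/25 -> weights 1.5/0.5
  ind <- tiny_individuals()[c(1, 4), ]
  ind$household_id <- c("h1", "h2"); ind$person_id <- c("p1", "p2")
  hh <- tiny_households(); hh$family_size <- c(1, 1)
  ds <- survey_dataset(rbind(ind,
                             transform(ind, person_id = c("p3", "p4"),
                                       household_id = c("h3", "h4"))),
                       rbind(hh, transform(hh, household_id = c("h3", "h4"))))
  dsw <- build_weights(ds, c(Cairo = 750, Alexandria = 250))
  w <- dsw$households$weight
  expect_equal(w[dsw$households$governorate == "Cairo"], c(1.5, 1.5))
  expect_equal(w[dsw$households$governorate == "Alexandria"], c(0.5, 0.5))
  expect_equal(mean(w), 1)
  # weighted stratum shares equal population shares exactly
  shares <- tapply(w, dsw$households$governorate, sum) / sum(w)
  expect_equal(as.numeric(shares[c("Cairo", "Alexandria")]), c(0.75, 0.25))
  # self-weighting design -> all weights 1
  dsu <- build_weights(ds, c(Cairo = 100, Alexandria = 100))
  expect_equal(dsu$households$weight, rep(1, 4))
  expect_error(build_weights(ds, c(Cairo = 1)), "Alexandria")
  expect_warning(build_weights(ds, c(Cairo = 1, Alexandria = 1, Giza = 50)),
                 "Giza")
})

test_that("required_sample_size reproduces the design worked example", {
  expect_identical(required_sample_size(0.5, 0.10, 0.05), 384L)
  # raw value 96.04 rounds half-down to 96 under the same rule that keeps
  # 384.16 at 384 (see package docs)
  expect_identical(required_sample_size(0.5, 0.20, 0.05), 96L)
  expect_error(required_sample_size(0, 0.1), "p must")
  expect_error(required_sample_size(0.5, -1), "rel_precision")
  expect_error(required_sample_size(0.5, 0.1, 1), "alpha")
  # degenerate bound: alpha -> 1 floors at n = 1
  expect_identical(required_sample_size(0.5, 0.1, 0.999), 1L)
  # monotone: non-increasing in rel_precision and alpha
  ns <- vapply(c(0.05, 0.1, 0.2, 0.4), function(d)
    required_sample_size(0.3, d, 0.05), integer(1))
  expect_true(all(diff(ns) <= 0))
  na <- vapply(c(0.01, 0.05, 0.1, 0.2), function(a)
    required_sample_size(0.3, 0.1, a), integer(1))
  expect_true(all(diff(na) <= 0))
})

test_that("cost ledger and population round-trip through YAML", {
  led <- cost_ledger(data.frame(service = c("out_public", "inp_public"),
                                total_spending = c(286000, 714000),
                                total_units = c(19067, 1428)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cost_ledger(led, path)
  led2 <- read_cost_ledger(path)
  expect_equal(as.data.frame(led2), as.data.frame(led))
  expect_error(cost_ledger(data.frame(service = "x", total_spending = 10,
                                      total_units = 0)), "total_units")
  ppath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(Cairo = 100, Giza = 50), ppath)
  expect_equal(read_population(ppath), c(Cairo = 100, Giza = 50))
})
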