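test_that("unit costs are spending over units and homogeneous of degree 0", {
  led <- cost_ledger(data.frame(service = c("out_public", "inp_public"),
                                total_spending = c(1000, 50000),
                                total_units = c(100, 100)))
  cu <- unit_costs(led)
  expect_equal(unname(cu["out_public"]), 10)
  led2 <- led; led2$total_spending <- 2 * led2$total_spending
  led2$total_units <- 2 * led2$total_units
  expect_equal(unit_costs(cost_ledger(led2)), cu)
})

test_that("annualization: 4-week recall scales by 13, yearly recall by 1", {
  expect_equal(annualization_factor(4), 13)
  expect_equal(annualization_factor(52), 1)
  expect_error(annualization_factor(0), "recall_weeks")
})

test_that("benefit arithmetic, zero-truncation and non-user zeros", {
  ind <- tiny_individuals()
  hh <- tiny_households()
  # person p1 uses public outpatient with oop 2.5 -> alpha 13
  ds <- survey_dataset(ind, hh)
  costs <- c(out_public = 100, inp_public = 500)
  # inflate an OOP beyond the unit cost to force truncation
  ds$individuals$oop_out_public[1] <- 130
  ben <- individual_benefits(ds, costs, alpha = c(out_public = 1,
                                                  inp_public = 1))
  b1 <- ben[ben$person_id == "p1" & ben$service == "out_public", ]
  expect_equal(b1$gross_benefit, 100)
  expect_equal(b1$net_benefit, 0)              # truncated, not negative
  # q=1, c=100, f=30, alpha=1 -> gross 100, net 70
  ds$individuals$oop_out_public[4] <- 30
  ben <- individual_benefits(ds, costs, alpha = c(out_public = 1))
  b4 <- ben[ben$person_id == "p4" & ben$service == "out_public", ]
  expect_equal(c(b4$gross_benefit, b4$net_benefit), c(100, 70))
  # default outpatient annualization: q=1, c=10, f=0 -> yearly gross 130
  ds0 <- survey_dataset(ind, hh)
  ds0$individuals$oop_out_public[] <- 0
  ben13 <- individual_benefits(ds0, c(out_public = 10))
  expect_equal(ben13$gross_benefit[ben13$service == "out_public" &
                                     ben13$q == 1], c(130, 130))
  # benefits are 0 for non-users; net <= gross elementwise
  ben_all <- individual_benefits(ds, costs)
  expect_true(all(ben_all$gross_benefit[ben_all$q == 0] == 0))
  expect_true(all(ben_all$net_benefit <= ben_all$gross_benefit + 1e-12))
  expect_true(all(ben_all$net_benefit >= 0))
  # unsubsidized (private) services carry zero program benefit
  expect_true(all(ben_all$gross_benefit[ben_all$service == "out_private"] == 0))
  ds_bad <- ds
  ds_bad$individuals$oop_out_public[1] <- 1     # then corrupt post-validation
  ben_rec <- ds_bad$individuals
  ben_rec$oop_out_public[1] <- -5
  ds_bad$individuals <- ben_rec
  expect_error(individual_benefits(ds_bad, costs), "negative OOP")
})

test_that("uniform benefits give equal shares and zero concentration", {
  cfg <- synthetic_config(seed = 5, n_households = 100)
  ds <- generate_survey(cfg)
  ds$individuals$use_out_public <- 1L
  ds$individuals$oop_out_public <- 0
  ranked <- rank_dataset(ds)
  # force an exactly uniform world: equal weights
  ranked$individuals$weight <- 1
  ben <- individual_benefits(ranked, c(out_public = 10))
  tab <- benefit_shares(ben, ranked, services = "out_public")
  shares <- unlist(tab[tab$type == "gross", paste0("Q", 1:5)])
  qw <- tapply(rep(1, nrow(ranked$individuals)),
               ranked$individuals$quintile, sum)
  expect_equal(unname(shares), as.numeric(100 * qw / sum(qw)),
               tolerance = 1e-10)
  expect_equal(tab$ci[tab$type == "gross"], 0, tolerance = 1e-12)
  expect_equal(sum(shares), 100, tolerance = 1e-10)
})

test_that("share columns sum to 100 and scaling costs leaves them unchanged", {
  ranked <- default_ranked()
  ben <- individual_benefits(ranked, c(out_public = 15, inp_public = 500))
  tab <- benefit_shares(ben, ranked)
  for (i in seq_len(nrow(tab)))
    expect_equal(sum(unlist(tab[i, paste0("Q", 1:5)])), 100,
                 tolerance = 0.1)
  # common scaling of all costs and OOP: shares and CIs unchanged
  ds2 <- ranked
  for (k in c("out_public", "out_private", "inp_public", "inp_private"))
    ds2$individuals[[paste0("oop_", k)]] <-
      7 * ds2$individuals[[paste0("oop_", k)]]
  ben2 <- individual_benefits(ds2, 7 * c(out_public = 15, inp_public = 500))
  tab2 <- benefit_shares(ben2, ds2)
  expect_equal(as.matrix(tab2[, paste0("Q", 1:5)]),
               as.matrix(tab[, paste0("Q", 1:5)]), tolerance = 1e-10)
  expect_equal(tab2$ci, tab$ci, tolerance = 1e-10)
  # net == gross when all OOP are zero
  ds0 <- ranked
  for (k in c("out_public", "inp_public"))
    ds0$individuals[[paste0("oop_", k)]][] <- 0
  ben0 <- individual_benefits(ds0, c(out_public = 15, inp_public = 500))
  tab0 <- benefit_shares(ben0, ds0)
  expect_equal(tab0$total[tab0$type == "net"],
               tab0$total[tab0$type == "gross"], tolerance = 1e-10)
})

test_that("ledger spending split drives the reported subsidy shares", {
  ranked <- default_ranked()
  led <- cost_ledger(data.frame(service = c("out_public", "inp_public"),
                                total_spending = c(28.6, 71.4) * 1e4,
                                total_units = c(19067, 1428)))
  ben <- individual_benefits(ranked, unit_costs(led))
  tab <- benefit_shares(ben, ranked, ledger = led)
  ss <- attr(tab, "subsidy_share")
  expect_equal(unname(ss[c("out_public", "inp_public")]), c(28.6, 71.4),
               tolerance = 1e-10)
})

test_that("benefit CI sign follows a monotone quintile-share gradient", {
  ranked <- default_ranked()
  ind <- ranked$individuals
  # construct a strictly pro-rich benefit: proportional to the rank
  rec <- data.frame(person_id = ind$person_id, service = "out_public",
                    q = 1L, unit_cost = 1, oop = 0,
                    gross_benefit = ind$frac_rank,
                    net_benefit = ind$frac_rank, stringsAsFactors = FALSE)
  class(rec) <- c("benefit_records", "data.frame")
  tab <- benefit_shares(rec, ranked, services = "out_public")
  shares <- unlist(tab[tab$type == "gross", paste0("Q", 1:5)])
  expect_true(all(diff(shares) > 0))
  expect_gt(tab$ci[1], 0)
})
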