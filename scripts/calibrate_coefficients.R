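#!/usr/bin/env Rscript
# Calibrates the synthetic generator's probit intercepts so that, at the
# default slope coefficients, the population means of chronic disease and of
# the four utilization indicators hit their target margins (NCD 0.204;
# use means 0.13 / 0.18 / 0.07 / 0.02). Large-n covariate simulation +
# root-finding; the resulting intercepts are frozen into
# R/synthetic_data.R (.default_util_coefs / .default_ncd_intercept).
#
#   Rscript scripts/calibrate_coefficients.R [n]

suppressPackageStartupMessages(library(equicat))

argv <- commandArgs(trailingOnly = TRUE)
n <- if (length(argv) >= 1) as.integer(argv[1]) else 400000L

cfg <- synthetic_config(seed = 42)
set.seed(202609)

# covariate population: age, gender, disability, consumption rank
ag <- sample(names(cfg$age_group_shares), n, replace = TRUE,
             prob = cfg$age_group_shares)
lo <- c("0-5" = 0, "6-17" = 6, "18-34" = 18, "35-64" = 35, "65+" = 65)
hi <- c("0-5" = 6, "6-17" = 18, "18-34" = 35, "35-64" = 65, "65+" = 85)
age <- runif(n, lo[ag], hi[ag])
female <- rbinom(n, 1, 1 - cfg$male_share)
dis <- rbinom(n, 1, cfg$disability_prevalence)
r <- runif(n)  # population consumption rank is uniform by construction

solve_intercept <- function(eta_no_int, target)
  uniroot(function(a) mean(pnorm(a + eta_no_int)) - target,
          c(-6, 2), tol = 1e-7)$root

m <- cfg$ncd_model
a_ncd <- solve_intercept(m["age_decade"] * age / 10 + m["rank"] * r,
                         cfg$ncd_prevalence)
cat(sprintf(".default_ncd_intercept: %.5f\n", a_ncd))
ncd <- rbinom(n, 1, pnorm(a_ncd + m["age_decade"] * age / 10 + m["rank"] * r))
cat(sprintf("  achieved NCD prevalence: %.4f (target %.3f)\n", mean(ncd),
            cfg$ncd_prevalence))

targets <- c(out_public = 0.13, out_private = 0.18,
             inp_public = 0.07, inp_private = 0.02)
for (k in names(targets)) {
  b <- cfg$utilization_coefficients[[k]]
  eta <- b["female"] * female + b["ncd"] * ncd + b["disability"] * dis +
    b["age_decade"] * age / 10 + b["rank"] * r
  a <- solve_intercept(eta, targets[k])
  cat(sprintf("%s intercept: %.5f  (achieved mean %.4f, target %.2f)\n",
              k, a, mean(pnorm(a + eta)), targets[k]))
}
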