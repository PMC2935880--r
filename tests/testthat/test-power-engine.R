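test_that("case/control frequencies follow the multiplicative model", {
  m <- effect_model(1.2)
  # null effect and fixed allele leave frequencies unchanged
  expect_equal(case_control_freqs(0.5, effect_model(1))$p_case, 0.5)
  expect_equal(case_control_freqs(1, effect_model(1.5))$p_case, 1)
  # p GRR / (p GRR + 1 - p) at p = 0.05, GRR = 1.2
  cc <- case_control_freqs(0.05, m)
  expect_equal(cc$p_case, 0.06 / 1.01, tolerance = 1e-12)
  expect_equal(cc$p_control, 0.05)
  expect_error(case_control_freqs(-0.1, m), "\\[0, 1\\]")
  expect_error(effect_model(0), "positive")
  expect_error(effect_model(1.2, prevalence = 1.5), "prevalence")
})

test_that("prevalence mode reduces to the rare-disease limit and shifts controls", {
  rare <- case_control_freqs(0.2, effect_model(1.3))
  tiny_k <- case_control_freqs(0.2, effect_model(1.3, prevalence = 1e-6))
  expect_equal(tiny_k$p_case, rare$p_case, tolerance = 1e-4)
  expect_equal(tiny_k$p_control, rare$p_control, tolerance = 1e-4)
  # at appreciable prevalence controls are depleted of the risk allele
  common_k <- case_control_freqs(0.2, effect_model(1.3, prevalence = 0.2))
  expect_lt(common_k$p_control, 0.2)
  expect_gt(common_k$p_case, common_k$p_control)
})

test_that("NCP vanishes under the null and scales linearly in sample size", {
  expect_equal(ncp_single(0.3, 5000, 5000, effect_model(1)), 0)
  expect_equal(ncp_single(0, 5000, 5000, effect_model(1.5)), 0)
  expect_equal(ncp_single(1, 5000, 5000, effect_model(1.5)), 0)
  expect_equal(ncp_single(0.3, 0, 5000, effect_model(1.5)), 0)
  n1 <- ncp_single(0.2, 5000, 5000, effect_model(1.3))
  n2 <- ncp_single(0.2, 10000, 10000, effect_model(1.3))
  expect_equal(n2, 2 * n1, tolerance = 1e-14)
})

test_that("the analytic NCP matches the Monte-Carlo mean-statistic identity", {
  # E[chi-square] = df + ncp under the alternative
  m <- effect_model(1.3)
  ncp <- ncp_single(0.2, 5000, 5000, m)
  mc <- monte_carlo_power(0.2, 5000, 5000, m, alpha = 0.05,
                          reps = 100000, seed = 3)
  # sd of the mean statistic ~ sd(chisq1(ncp))/sqrt(reps) = sqrt(2+4ncp)/sqrt(reps)
  se <- sqrt(2 + 4 * ncp) / sqrt(mc$reps)
  expect_lt(abs(mc$mean_stat - (1 + ncp)), 4 * se)
})

test_that("power from the NCP has exact size and the 1-df closed form", {
  expect_identical(power_from_ncp(0, alpha = 0.05), 0.05)
  expect_identical(power_from_ncp(0, alpha = 5e-8), 5e-8)
  for (alpha in c(0.05, 5e-8)) {
    z <- qnorm(1 - alpha / 2)
    for (ncp in c(0.1, 1, 10, 50)) {
      closed <- pnorm(sqrt(ncp) - z) + pnorm(-sqrt(ncp) - z)
      expect_lt(abs(power_from_ncp(ncp, alpha) - closed), 1e-10)
    }
  }
  expect_error(power_from_ncp(-1), "non-negative")
  expect_error(power_from_ncp(1, alpha = 0), "alpha")
})

test_that("two-phase SNP power sums NCPs and averages allele orientations", {
  m <- effect_model(1.2)
  freqs <- c(CEU = 0.2, YRI = 0.4)
  # monomorphic in every scenario panel: power equals the size
  sc <- scenario("s", phase_design("CEU", 5000, 5000),
                 phase_design("CEU", 5000, 5000))
  expect_equal(snp_power(c(CEU = 0), sc, m, alpha = 5e-8), 5e-8)
  # two same-panel phases of n equal one phase of 2n
  sc1 <- scenario("one", phase_design("CEU", 10000, 10000))
  expect_equal(snp_power(freqs, sc, m), snp_power(freqs, sc1, m),
               tolerance = 1e-12)
  # at GRR = 1 both orientations coincide with the average
  expect_equal(snp_power(freqs, sc, effect_model(1), risk_allele = "average"),
               snp_power(freqs, sc, effect_model(1), risk_allele = "a"))
  expect_error(snp_power(c(CEU = 0.2), scenario(
    "x", phase_design("YRI", 100, 100)), m), "YRI")
})

test_that("a common allele in the second-phase panel rescues power", {
  # motivated by loci rare in Europeans but common in East Asians:
  # p = 0.05 in the European panel, 0.40 in the East-Asian panel, GRR 1.2
  m <- effect_model(1.2)
  freqs <- c(EUR = 0.05, EAS = 0.40)
  p1 <- phase_design("EUR", 10000, 10000)
  pow_eas <- snp_power(freqs, scenario("eas", p1,
                                       phase_design("EAS", 10000, 10000)), m)
  pow_eur <- snp_power(freqs, scenario("eur", p1,
                                       phase_design("EUR", 10000, 10000)), m)
  expect_gt(pow_eas, pow_eur)
})

test_that("power is monotone in effect size, sample size and alpha", {
  ps <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5)
  grrs <- c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5)
  for (alpha in c(0.05, 5e-8)) {
    pw <- sapply(grrs, function(g) {
      power_from_ncp(ncp_single(ps, 2500, 2500, effect_model(g)), alpha)
    })
    expect_true(all(diff(t(pw)) >= -1e-15))          # in GRR
  }
  for (g in c(1.1, 1.3)) {
    pw_n <- sapply(c(1000, 2000, 4000, 8000), function(n) {
      power_from_ncp(ncp_single(ps, n, n, effect_model(g)))
    })
    expect_true(all(diff(t(pw_n)) >= -1e-15))        # in sample size
    pw_a <- sapply(c(5e-8, 1e-5, 1e-3, 0.05), function(a) {
      power_from_ncp(ncp_single(ps, 2500, 2500, effect_model(g)), a)
    })
    expect_true(all(diff(t(pw_a)) >= -1e-15))        # in alpha
  }
})

test_that("the Monte-Carlo oracle is calibrated, deterministic and agrees", {
  mc0 <- monte_carlo_power(0.3, 1000, 1000, effect_model(1), alpha = 0.05,
                           reps = 50000, seed = 5)
  expect_lt(abs(mc0$power - 0.05), 3 * sqrt(0.05 * 0.95 / 50000))
  mc1 <- monte_carlo_power(0.3, 2500, 2500, effect_model(1.4),
                           alpha = 0.05, reps = 50000, seed = 8)
  analytic <- power_from_ncp(
    ncp_single(0.3, 2500, 2500, effect_model(1.4)), alpha = 0.05)
  expect_lt(abs(mc1$power - analytic),
            3 * sqrt(analytic * (1 - analytic) / 50000))
  mc1b <- monte_carlo_power(0.3, 2500, 2500, effect_model(1.4),
                            alpha = 0.05, reps = 50000, seed = 8)
  expect_identical(mc1, mc1b)
})
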