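test_that("treatment-effect points follow (1 - HR) x 100 with the 0.8 PFS weight", {
  expect_equal(treatment_effect_points(0.49, "OS"), 51)
  expect_equal(treatment_effect_points(0.52, "PFS"), 38.4)
  expect_equal(treatment_effect_points(0.65, "RFS_DFS", "curative"), 35)
  expect_equal(treatment_effect_points(1.0, "OS"), 0)
  expect_lt(treatment_effect_points(1.2, "OS"), 0)  # harm is not floored
  expect_error(treatment_effect_points(0, "OS"), "positive")
  expect_error(treatment_effect_points(-0.5, "OS"), "positive")

  # strictly decreasing in HR; PFS is exactly 0.8 x OS at equal HR
  hrs <- seq(0.2, 1.4, by = 0.05)
  os <- vapply(hrs, treatment_effect_points, 0, endpoint = "OS")
  pfs <- vapply(hrs, treatment_effect_points, 0, endpoint = "PFS")
  expect_true(all(diff(os) < 0))
  expect_equal(pfs, 0.8 * os)
})

test_that("toxicity points scale the relative burden difference into [-20, 20]", {
  tab <- function(bc, be) data.frame(ae = "total", inc_control = bc,
                                     inc_experimental = be)
  expect_equal(toxicity_points(tab(0.4, 0.4)), 0)
  expect_equal(toxicity_points(tab(0.6, 0.3)), 10)           # 20 * 0.3 / 0.6
  expect_equal(toxicity_points(tab(0.1, 0.9)), -20 * 0.8 / 0.9)  # -17.78
  expect_equal(toxicity_points(tab(0, 0)), 0)
  expect_equal(toxicity_points(tab(0.5, 0)), 20)
  expect_equal(toxicity_points(tab(0, 0.5)), -20)
  expect_equal(toxicity_points(override = -7.5), -7.5)
  expect_error(toxicity_points(), "no toxicity inputs")
  expect_error(toxicity_points(override = 25), "\\[-20, 20\\]")
})

test_that("toxicity points are antisymmetric under arm swap and bounded", {
  set.seed(101)
  for (i in 1:200) {
    t1 <- random_toxicity_table(n = sample(1:10, 1))
    s1 <- toxicity_points(t1)
    s2 <- toxicity_points(swap_arms(t1))
    expect_equal(s2, -s1, tolerance = 1e-12)
    expect_true(abs(s1) <= 20)
  }
})

test_that("tail-of-the-curve bonus applies the 50%-improvement and 20%-floor gates", {
  lm <- function(t, sc, se) data.frame(time = t, surv_control = sc,
                                       surv_experimental = se)
  expect_equal(as.numeric(tail_of_curve_bonus("OS", 1, lm(2, 0.25, 0.40))), 20)
  expect_equal(as.numeric(tail_of_curve_bonus("PFS", 1, lm(2, 0.25, 0.40))), 16)
  expect_equal(as.numeric(tail_of_curve_bonus("RFS_DFS", 1, lm(2, 0.25, 0.40))), 20)
  # 20% floor fails regardless of the experimental arm
  expect_equal(as.numeric(tail_of_curve_bonus("OS", 1, lm(2, 0.15, 0.99))), 0)
  # below a 50% relative improvement
  expect_equal(as.numeric(tail_of_curve_bonus("OS", 1, lm(2, 0.30, 0.44))), 0)
  # boundary: exactly 1.5x qualifies
  expect_equal(as.numeric(tail_of_curve_bonus("OS", 1, lm(2, 0.30, 0.45))), 20)
  # landmark matching within +/-10% of twice the control median
  expect_equal(as.numeric(tail_of_curve_bonus("OS", 10, lm(21, 0.25, 0.40))), 20)
  b <- tail_of_curve_bonus("OS", 10, lm(25, 0.25, 0.40))
  expect_equal(as.numeric(b), 0)
  expect_match(attr(b, "reason"), "not assessable")
  expect_match(attr(tail_of_curve_bonus("OS", NA, lm(2, 0.3, 0.5)), "reason"),
               "not assessable")
  expect_match(attr(tail_of_curve_bonus("OS", 10, NULL), "reason"),
               "not assessable")
})

test_that("tail bonus is monotone in the survival proportions", {
  set.seed(202)
  for (i in 1:200) {
    mc <- runif(1, 3, 20)
    sc <- runif(1, 0.05, 0.6)
    se <- runif(1, sc, min(1, 3 * sc))
    lm <- function(sc, se) data.frame(time = 2 * mc, surv_control = sc,
                                      surv_experimental = se)
    base <- as.numeric(tail_of_curve_bonus("OS", mc, lm(sc, se)))
    # raising experimental survival never revokes a bonus
    better <- as.numeric(tail_of_curve_bonus("OS", mc,
                                             lm(sc, min(1, se + 0.1))))
    expect_gte(better, base)
    # dropping control survival below the floor always revokes it
    expect_equal(as.numeric(tail_of_curve_bonus("OS", mc, lm(0.19, se))), 0)
  }
})

test_that("score_asco composes components, overrides and flags into the NHB", {
  rec <- make_record(hr = 0.73, ci_lower = 0.59, ci_upper = 0.91,
                     toxicity_points_override = 1.0, tail_bonus_override = 20)
  b <- score_asco(rec)
  expect_equal(b$nhb, 48.0)
  expect_equal(b$nhb, b$treatment_effect_points + b$toxicity_points +
                 b$tail_bonus + b$palliation_bonus + b$qol_bonus + b$tfi_bonus)

  # flags: palliation + QOL + TFI each worth a flat 10
  rec2 <- make_record(hr = 0.70, ci_lower = 0.52, ci_upper = 0.92,
                      toxicity_points_override = 7.1,
                      tail_bonus_override = 20, qol = "improved",
                      palliation_improved = TRUE)
  b2 <- score_asco(rec2)
  expect_equal(c(b2$palliation_bonus, b2$qol_bonus, b2$tfi_bonus),
               c(10, 10, 0))
  expect_equal(b2$nhb, 77.1)

  # null effect, zero burden, no bonuses
  rec3 <- make_record(hr = 1, ci_lower = 0.8, ci_upper = 1.25,
                      toxicity_table = data.frame(
                        ae = "x", inc_control = 0, inc_experimental = 0),
                      tail_bonus_override = 0)
  expect_equal(score_asco(rec3)$nhb, 0)

  # raw-data tail path inside score_asco
  rec4 <- make_record(hr = 0.6, ci_lower = 0.5, ci_upper = 0.75,
                      median_control = 6,
                      landmark_survival = data.frame(
                        time = 12, surv_control = 0.25,
                        surv_experimental = 0.40),
                      toxicity_points_override = 0)
  expect_equal(score_asco(rec4)$tail_bonus, 20)

  # no toxicity inputs at all is a scoring error
  expect_error(score_asco(make_record()), "no toxicity inputs")

  # a transcribed bonus conflicting with the endpoint award level is logged
  rec5 <- make_record(endpoint = "OS", toxicity_points_override = 0,
                      tail_bonus_override = 16)
  expect_true(any(grepl("differs from the 20-point award level",
                        score_asco(rec5)$notes)))
})

test_that("score_asco reproduces every published initial-phase score breakdown", {
  fx <- load_fixtures("initial")
  exp <- fx$expected
  for (k in seq_along(fx$records)) {
    b <- score_asco(fx$records[[k]])
    i <- match(b$trial_id, exp$trial_id)
    expect_equal(round(b$treatment_effect_points, 1),
                 exp$exp_treatment_effect[i], info = b$trial_id)
    expect_equal(b$toxicity_points, exp$exp_toxicity[i], info = b$trial_id)
    expect_equal(b$tail_bonus, exp$exp_tail[i], info = b$trial_id)
    expect_true(abs(b$nhb - exp$exp_nhb[i]) <= 0.15, info = b$trial_id)
  }
})
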