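# Brute-force step-up oracle for the BH test.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04),
               tolerance = 1e-12)
  p_flat <- rep(0.2, 6)
  expect_equal(bh_fdr(p_flat), p_flat)
  withr::with_seed(10, {
    for (i in 1:200) {
      p <- runif(sample(1:40, 1))
      q <- bh_fdr(p)
      expect_equal(q, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-15))
      ord <- order(p)
      expect_true(all(diff(q[ord]) >= -1e-15))
    }
  })
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

surv_data <- function(n, beta, seed, horizon = 15, h0 = 0.024) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    t_ev <- rexp(n, h0 * exp(beta * x))
    tibble::tibble(subject_id = as.character(1:n), x = x,
                   time = pmin(t_ev, horizon),
                   event = as.integer(t_ev <= horizon),
                   cov = rnorm(n))
  })
}

test_that("Cox per-1-s.d. estimates are invariant to exposure rescaling", {
  d <- surv_data(2000, log(1.5), seed = 1)
  r1 <- fit_cox(d, "time", "event", "x", covariates = "cov")
  d2 <- dplyr::mutate(d, x = 3.7 * x)
  r2 <- fit_cox(d2, "time", "event", "x", covariates = "cov")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
  expect_true(r1$conf.low < r1$estimate && r1$estimate < r1$conf.high)
})

test_that("a null exposure gives a hazard ratio near one", {
  d <- surv_data(2000, 0, seed = 2)
  r <- fit_cox(d, "time", "event", "x")
  expect_lt(abs(r$log_hr), 0.1)
})

test_that("too few events is an error, not a silent fit", {
  d <- surv_data(2000, 0, seed = 3, horizon = 0.05)
  expect_error(fit_cox(d, "time", "event", "x"), "events")
})

test_that("logistic ORs invert exactly under label inversion", {
  d <- withr::with_seed(4, {
    x <- rnorm(1500)
    tibble::tibble(y = rbinom(1500, 1, plogis(-1 + 0.5 * x)), x = x)
  })
  r <- fit_logistic(d, "y", "x")
  r_inv <- fit_logistic(dplyr::mutate(d, y = 1L - y), "y", "x")
  expect_equal(r$estimate, 1 / r_inv$estimate, tolerance = 1e-6)
  expect_error(fit_logistic(dplyr::mutate(d, y = 1L), "y", "x"), "classes")
})

test_that("logistic recovery of a generating log-odds coefficient", {
  d <- withr::with_seed(5, {
    x <- rnorm(5000)
    tibble::tibble(y = rbinom(5000, 1, plogis(-1 + 0.5 * x)), x = x)
  })
  r <- fit_logistic(d, "y", "x")
  expect_lt(abs(r$log_or - 0.5), 0.1)
})

test_that("relative contributions scale |z| of significant terms to one", {
  res <- tibble::tibble(outcome = "mortality",
                        exposure = c("brain", "kidney", "heart", "lung"),
                        z = c(6, 3, 1, 2), q = c(0.001, 0.01, 0.02, 0.5),
                        flagged = FALSE)
  prof <- relative_contribution(res, alpha = 0.05)
  expect_equal(prof$weight[match(c("brain", "kidney", "heart"),
                                 prof$exposure)], c(0.6, 0.3, 0.1))
  expect_equal(sum(prof$weight), 1)
  single <- relative_contribution(res[1, ], alpha = 0.05)
  expect_equal(single$weight, 1)
  none <- relative_contribution(dplyr::mutate(res, q = 0.9))
  expect_equal(nrow(none), 0)
  expect_false(anyNA(none$weight))
  expect_error(relative_contribution(dplyr::mutate(res,
    outcome = c("a", "a", "b", "b"))), "single outcome")
})

test_that("association families carry BH q-values and their definition", {
  d <- surv_data(1500, log(1.4), seed = 6)
  d$x2 <- withr::with_seed(7, rnorm(1500))
  fam <- tibble::tibble(outcome = "death", type = "survival",
                        time = "time", event = "event")
  res <- run_associations(d, fam, exposures = c("x", "x2"),
                          covariates = "cov")
  expect_equal(nrow(res), 2)
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  expect_named(attr(res, "family"), c("outcomes", "exposures",
                                      "covariates", "m"))
})

test_that("MCI and distress transition rules use the stated thresholds", {
  # reference group engineered to have mean 0 and s.d. 1 exactly, so the
  # MCI threshold is -1.5 on the raw scale
  ref <- c(-1.5, -0.5, 0.5, 1.5) / sqrt(5 / 3)
  d <- tibble::tibble(
    subject_id = as.character(1:8),
    score = c(ref, -1.6, -1.4, -1.5, 0.3),
    edu = rep("low", 8),
    normal = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    phq4 = c(0, 2, 5, 6, 7, 3, 6, 12)
  )
  out <- define_transitions(d, "score", "edu", "normal",
                            distress_score = "phq4")
  expect_true(out$mci[5])     # -1.6: below threshold
  expect_false(out$mci[6])    # -1.4: inside
  expect_true(out$mci[7])     # boundary -1.5 is inclusive
  expect_equal(out$distress, d$phq4 >= 6)
  # stratum with < 2 reference subjects is skipped with a warning
  d_small <- dplyr::mutate(d, edu = c("low", rep("hi", 7)))
  expect_warning(out2 <- define_transitions(d_small, "score", "edu",
                                            "normal"), "low")
  expect_true(is.na(out2$mci[1]))
})

test_that("multimorbidity requires two incident diseases per category", {
  cmap <- tibble::tibble(
    disease = c("mi", "stroke", "depression", "anxiety"),
    category = c("physical", "physical", "neuropsychiatric",
                 "neuropsychiatric"))
  inc <- tibble::tibble(
    subject_id = c("a", "a", "b", "b", "c"),
    disease = c("mi", "stroke", "mi", "depression", "anxiety"))
  out <- define_multimorbidity(inc, cmap, subjects = c("a", "b", "c", "d"))
  get <- function(s, cat) out$multimorbid[out$subject_id == s &
                                          out$category == cat]
  expect_true(get("a", "physical"))
  expect_true(get("a", "combined"))
  expect_false(get("b", "physical"))
  expect_false(get("b", "neuropsychiatric"))
  expect_true(get("b", "combined"))       # 1 + 1 across categories
  expect_false(any(out$multimorbid[out$subject_id == "d"]))
  expect_equal(out$n_diseases[out$subject_id == "d" &
                              out$category == "combined"], 0L)
  expect_error(define_multimorbidity(
    tibble::tibble(subject_id = "a", disease = "unknown"), cmap), "unknown")
})

test_that("matched controls satisfy the constraints without reuse", {
  pool <- withr::with_seed(8, tibble::tibble(
    subject_id = sprintf("C%04d", 1:2000),
    age = runif(2000, 37, 70),
    sex = factor(sample(c("female", "male"), 2000, replace = TRUE))))
  cases <- withr::with_seed(9, tibble::tibble(
    subject_id = sprintf("X%02d", 1:20),
    age = runif(20, 45, 60),
    sex = factor(sample(c("female", "male"), 20, replace = TRUE))))
  m <- match_controls(cases, pool, ratio = 5, age_tolerance = 2, seed = 1)
  expect_equal(nrow(m), 100)            # abundant pool: exactly 5 per case
  expect_equal(anyDuplicated(m$control_id), 0)
  joined <- dplyr::left_join(m, pool,
                             by = c(control_id = "subject_id")) |>
    dplyr::left_join(cases, by = c(case_id = "subject_id"),
                     suffix = c("_ctrl", "_case"))
  expect_true(all(abs(joined$age_ctrl - joined$age_case) <= 2))
  expect_true(all(joined$sex_ctrl == joined$sex_case))
  expect_identical(m, match_controls(cases, pool, seed = 1))
  expect_error(match_controls(cases, pool[0, ]), "empty")
})

test_that("AUC equals the rank statistic and handles separation", {
  d <- withr::with_seed(11, tibble::tibble(
    y = rep(0:1, each = 100),
    perfect = rep(c(0, 10), each = 100) + runif(200),
    noise = rnorm(200)))
  res <- compare_auc(d, "y", list(perfect = "perfect", noise = "noise"),
                     n_boot = 50, seed = 1)
  expect_equal(res$auc$auc[res$auc$model == "perfect"], 1.0)
  expect_lt(abs(res$auc$auc[res$auc$model == "noise"] - 0.5), 0.15)
  expect_lt(res$pairwise$p, 0.1)
  skip_if_not_installed("pROC")
  a_pkg <- as.numeric(pROC::auc(pROC::roc(d$y, d$noise, quiet = TRUE,
                                          direction = "<")))
  r <- rank(d$noise)
  a_rank <- (sum(r[d$y == 1]) - 100 * 101 / 2) / (100 * 100)
  expect_equal(a_rank, a_pkg, tolerance = 1e-12)
})

test_that("cumulative incidence matches closed forms", {
  # all events at distinct times, no censoring: steps of 1/n
  d <- tibble::tibble(time = 1:10, event = 1L, grp = "all")
  ci <- cumulative_incidence(d, "time", "event", "grp")
  expect_equal(ci$cuminc, (1:10) / 10, tolerance = 1e-12)
  # no events: flat zero
  d0 <- tibble::tibble(time = 1:10, event = 0L, grp = "all")
  ci0 <- cumulative_incidence(d0, "time", "event", "grp")
  expect_true(all(ci0$cuminc == 0))
  # empty factor level skipped with a warning
  d2 <- dplyr::mutate(d, grp = factor("a", levels = c("a", "b")))
  expect_warning(cumulative_incidence(d2, "time", "event", "grp"), "b")
})

test_that("a higher-hazard group dominates the incidence curve", {
  d <- withr::with_seed(12, {
    g <- rep(c("hi", "lo"), each = 1000)
    rate <- ifelse(g == "hi", 0.09, 0.03)
    t_ev <- rexp(2000, rate)
    tibble::tibble(time = pmin(t_ev, 15), event = as.integer(t_ev <= 15),
                   grp = g)
  })
  ci <- cumulative_incidence(d, "time", "event", "grp")
  final <- dplyr::summarise(dplyr::group_by(ci, group),
                            top = max(cuminc))
  expect_gt(final$top[final$group == "hi"], final$top[final$group == "lo"])
})

test_that("lifestyle categories follow the 0-2 / 3-5 / 6-9 cut points", {
  expect_equal(as.character(lifestyle_category(c(0, 2, 3, 5, 6, 9))),
               c("favorable", "favorable", "intermediate", "intermediate",
                 "unfavorable", "unfavorable"))
  expect_error(lifestyle_category(10), "\\[0, 9\\]")
  expect_error(lifestyle_category(-1), "\\[0, 9\\]")
})

test_that("the Schoenfeld check flags a time-varying effect", {
  d_ok <- surv_data(1500, log(1.5), seed = 13)
  fit_ok <- attr(fit_cox(d_ok, "time", "event", "x"), "fit")
  zph_ok <- check_proportional_hazards(fit_ok)
  expect_gt(zph_ok$p[zph_ok$term == ".exposure_z"], 0.01)
  # crossing hazards: effect reverses between early and late epochs
  d_tv <- withr::with_seed(14, {
    x <- rnorm(2000)
    early <- rexp(2000, 0.3 * exp(1.2 * x))
    late <- 5 + rexp(2000, 0.3 * exp(-1.2 * x))
    t_ev <- ifelse(early <= 5, early, late)
    tibble::tibble(x = x, time = pmin(t_ev, 15),
                   event = as.integer(t_ev <= 15))
  })
  fit_tv <- attr(fit_cox(d_tv, "time", "event", "x"), "fit")
  zph_tv <- check_proportional_hazards(fit_tv)
  expect_lt(zph_tv$p[zph_tv$term == ".exposure_z"], 0.01)
})
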