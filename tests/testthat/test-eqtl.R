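test_that("sharing decomposition reproduces hand counts and the exact
           identity", {
  # w = (0.7, 0.3), p_c = (0.9, 0.2)  ->  p = 0.69
  rec <- data.frame(
    category = rep(c("a", "b"), c(70, 30)),
    shared = c(rep(c(TRUE, FALSE), c(63, 7)), rep(c(TRUE, FALSE), c(6, 24))),
    stringsAsFactors = FALSE)
  d <- decompose_sharing(rec)
  expect_equal(d$p, 0.69)
  expect_equal(d$table$w, c(0.7, 0.3))
  expect_equal(d$table$p_c, c(0.9, 0.2))
  expect_equal(sum(d$table$p_c * d$table$w), d$p)

  # single category: p equals p_c
  rec1 <- data.frame(category = "a", shared = c(TRUE, TRUE, FALSE))
  d1 <- decompose_sharing(rec1)
  expect_equal(d1$p, d1$table$p_c)

  expect_error(decompose_sharing(rec[0, ]), "empty")

  # brute-force oracle on a small random table, plus the exact identity
  set.seed(4)
  for (r in 1:10) {
    rr <- data.frame(category = sample(letters[1:4], 20, replace = TRUE),
                     shared = sample(c(TRUE, FALSE), 20, replace = TRUE))
    dd <- decompose_sharing(rr)
    for (cc in unique(rr$category)) {
      expect_equal(dd$table$p_c[dd$table$category == cc],
                   mean(rr$shared[rr$category == cc]))
      expect_equal(dd$table$w[dd$table$category == cc],
                   mean(rr$category == cc))
    }
    expect_equal(dd$p, sum(dd$table$p_c * dd$table$w), tolerance = 1e-15)
    expect_equal(sum(dd$table$w), 1, tolerance = 1e-15)
  }
})

test_that("per-category tissue-count summaries match direct computation", {
  rec <- data.frame(category = c(rep("cm", 3), rep("fibro", 4)),
                    n_tissues_active = c(5L, 31L, 43L, 2L, 3L, 40L, 41L))
  s <- sharing_summary(rec)
  expect_equal(s$median[s$category == "cm"], 31)
  expect_equal(s$median[s$category == "fibro"], median(c(2, 3, 40, 41)))
  expect_equal(s$q1[s$category == "cm"],
               as.numeric(quantile(c(5, 31, 43), 0.25)))

  recf <- rec
  recf$category <- factor(recf$category, levels = c("cm", "fibro", "empty"))
  expect_warning(sharing_summary(recf), "empty")
})

test_that("category enrichment recovers known folds and flags degeneracies", {
  e <- data.frame(category = rep(c("cm", "bg"), c(26, 74)))
  ctl <- data.frame(category = rep(c("cm", "bg"), c(1, 99)))
  fe <- suppressWarnings(category_enrichment(e, ctl))
  expect_equal(fe$fold[fe$category == "cm"], 26)

  # identical distributions give folds of 1
  fe1 <- suppressWarnings(category_enrichment(e, e))
  expect_equal(fe1$fold, c(1, 1))

  # invariance to duplicating the control set
  fe2 <- suppressWarnings(category_enrichment(e, rbind(ctl, ctl)))
  expect_equal(fe2$fold, fe$fold)

  # zero control proportion
  e0 <- data.frame(category = rep(c("cm", "new"), c(26, 4)))
  fe0 <- suppressWarnings(category_enrichment(e0, ctl))
  expect_true(is.infinite(fe0$fold[fe0$category == "new"]))
  expect_true(fe0$fold_undefined[fe0$category == "new"])

  expect_warning(category_enrichment(e, ctl[1:5, , drop = FALSE]), "small")
})

test_that("simulated eQTL records reproduce their generating folds and
           sharing", {
  sim <- simulate_eqtl_records(n_eqtl = 4000, n_control = 20000, seed = 31)
  fe <- category_enrichment(sim$eqtls, sim$controls)
  truth <- sim$truth$folds
  for (cc in names(truth)) {
    got <- fe$fold[fe$category == cc]
    expect_lt(abs(got - truth[[cc]]) / truth[[cc]], 0.35)
  }
  d <- decompose_sharing(sim$eqtls)
  for (cc in d$table$category) {
    expect_lt(abs(d$table$p_c[d$table$category == cc] -
                    sim$truth$p_share[[cc]]), 0.12)
  }
  # records respect the fine-mapping retention rule
  expect_true(all(sim$eqtls$pip >= 0.8))
})

test_that("the dilution power ratio matches the analytic oracle", {
  # f = 1: specific and shared models coincide up to Monte-Carlo noise
  s1 <- power_ratio_simulation(1, effect_grid = 0.25, reps = 2000, seed = 2)
  expect_lt(abs(s1$ratio - 1), 0.05)

  s <- power_ratio_simulation(0.4, effect_grid = c(0.2, 0.3), n = 200,
                              reps = 2000, seed = 3)
  a <- power_ratio_normal_approx(0.4, beta = c(0.2, 0.3), n = 200)
  expect_lt(max(abs(s$ratio - a$ratio)), 0.05)
  expect_true(all(s$ratio <= 1 + 0.05))

  expect_error(power_ratio_simulation(0, 0.2, reps = 2000, seed = 1),
               "f must be")
  expect_error(power_ratio_simulation(1.2, 0.2, reps = 2000, seed = 1),
               "f must be")
  expect_error(power_ratio_simulation(0.5, 0.2, reps = 10, seed = 1),
               "reps")
})

test_that("the eQTL mixture dilutes the bulk slope by the cell fraction", {
  sim <- simulate_eqtl_mixture(n = 20000, beta = 0.5, cell_fraction = 0.2,
                               specific = TRUE, seed = 12)
  fit <- lm(expression ~ genotype, data = sim$data)
  expect_lt(abs(unname(coef(fit)[2]) - 0.1), 0.035)
  expect_equal(sim$truth$bulk_slope, 0.1)
  expect_error(simulate_eqtl_mixture(cell_fraction = 0), "cell_fraction")
})
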