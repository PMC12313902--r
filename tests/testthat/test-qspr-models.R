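test_that("an exact line is recovered with R-squared 1", {
  fit <- fit_polynomial(c(0, 1, 2), c(1, 3, 5), 1)
  expect_equal(unname(fit$coefficients), c(1, 2))
  expect_equal(fit$stats$R_squared, 1)
  expect_equal(fit$stats$RSS, 0, tolerance = 1e-20)
})

test_that("the boiling-point fit on the drug table matches the published panel", {
  d <- load_drug_table()
  fit <- fit_polynomial(d$M1, d$BP, 1, "M1", "BP")
  expect_equal(unname(fit$coefficients), c(324.9636, 1.8616), tolerance = 1e-4)
  expect_equal(fit$stats$R_squared, 0.877, tolerance = 0.001)
  expect_equal(fit$stats$F_stat, 106.525, tolerance = 1e-3)
  expect_lt(fit$stats$p_value, 1e-6)
  # published fitted values, 1 d.p.: Lenalidomide, Cabozantinib
  expect_equal(round(predict(fit, 104), 1), 518.6)
  expect_equal(round(predict(fit, 200), 1), 697.3)
  expect_equal(predict(fit, 0), unname(fit$coefficients[1]))
})

test_that("OLS coefficients equal the normal-equations oracle on random draws", {
  set.seed(21)
  for (i in 1:50) {
    x <- rnorm(25, sd = 2)
    y <- rnorm(25)
    for (deg in c(1, 3)) {
      fit <- fit_polynomial(x, y, deg)
      expect_equal(unname(fit$coefficients), ols_normal_equations(x, y, deg),
                   tolerance = 1e-6)
      # residuals orthogonal to every design column
      r <- y - predict(fit, x)
      for (j in 0:deg)
        expect_lt(abs(sum(r * x^j)) / max(1, sum(abs(y))), 1e-7)
    }
  }
})

test_that("the fitted line passes through the data centroid", {
  set.seed(3)
  x <- runif(30, 0, 10); y <- 2 + 0.5 * x + rnorm(30)
  fit <- fit_polynomial(x, y, 1)
  expect_equal(predict(fit, mean(x)), mean(y), tolerance = 1e-12)
})

test_that("statistics panel follows its defining formulas and rejects degenerate input", {
  set.seed(4)
  x <- runif(20, 0, 5); y <- 1 + x + rnorm(20)
  fit <- fit_polynomial(x, y, 3)
  s <- fit$stats
  expect_equal(s$R, sqrt(s$R_squared))
  expect_equal(s$F_stat, (s$R_squared / 3) / ((1 - s$R_squared) / (20 - 4)))
  expect_equal(s$S_E, sqrt(s$RSS / (20 - 4)))
  expect_equal(s$p_value, pf(s$F_stat, 3, 16, lower.tail = FALSE))

  expect_error(fit_polynomial(x, rep(2, 20), 1), "constant response")
  expect_error(fit_polynomial(rep(1, 10), rnorm(10), 1), "rank-deficient|distinct")
  expect_error(fit_polynomial(c(1, 2, 3), c(1, 2, 3), 3), "observations")
  expect_error(fit_polynomial(c(1, 1, 2, 2, 3, 3), rnorm(6), 3), "distinct")
})

test_that("cubic never has lower R-squared than linear on the same data", {
  set.seed(6)
  for (i in 1:20) {
    x <- runif(17, 0, 10)
    y <- sin(x) + rnorm(17, sd = 0.3)
    r1 <- fit_polynomial(x, y, 1)$stats$R_squared
    r3 <- fit_polynomial(x, y, 3)$stats$R_squared
    expect_gte(r3 + 1e-12, r1)
  }
})

test_that("linear-fit statistics are invariant under affine rescaling of x", {
  set.seed(8)
  x <- runif(17, 100, 1000); y <- 3 + 0.02 * x + rnorm(17, sd = 2)
  f0 <- fit_polynomial(x, y, 1)
  f1 <- fit_polynomial((x - 50) / 7, y, 1)
  expect_equal(f1$stats$R_squared, f0$stats$R_squared, tolerance = 1e-10)
  expect_equal(f1$stats$F_stat, f0$stats$F_stat, tolerance = 1e-8)
  expect_equal(f1$stats$p_value, f0$stats$p_value, tolerance = 1e-8)
  # slope transforms by the scale factor, intercept absorbs the shift
  expect_equal(f1$coefficients[["beta1"]], f0$coefficients[["beta1"]] * 7,
               tolerance = 1e-8)
})

test_that("slope estimates land within sampling error of the truth", {
  set.seed(31)
  hits <- 0L
  for (r in 1:200) {
    x <- runif(40, 0, 10)
    y <- 1 + 2 * x + rnorm(40, sd = 1.5)
    fit <- fit_polynomial(x, y, 1)
    se_b1 <- fit$stats$S_E / sqrt(sum((x - mean(x))^2))
    if (abs(fit$coefficients[["beta1"]] - 2) <= 4 * se_b1) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99)
})

test_that("qspr_table lays out 14 rows per index and validates its input", {
  d <- load_drug_table()
  tab <- qspr_table(d, "M1")
  expect_equal(nrow(tab), 14)
  expect_setequal(unique(tab$form), c("linear", "cubic"))
  bp_lin <- tab[tab$property == "BP" & tab$form == "linear", ]
  expect_equal(bp_lin$beta0, 324.9636, tolerance = 1e-4)
  expect_equal(bp_lin$beta1, 1.8616, tolerance = 1e-4)
  expect_true(is.na(bp_lin$beta3))

  h_mr <- qspr_table(d, "H")
  expect_equal(h_mr[h_mr$property == "MR" & h_mr$form == "linear", "R_squared"],
               0.985, tolerance = 0.002)

  expect_error(qspr_table(d[1:2, ], "M1"), "at least 5")
  expect_error(qspr_table(d, "XX"), "unknown index")
  expect_error(qspr_table(d, "M1", properties = "QQ"), "unknown property")
})

test_that("prediction_table reports actuals and per-index fitted values", {
  d <- load_drug_table()
  tab <- prediction_table(d, "BP")
  expect_equal(nrow(tab), 1 + 10 * 2)
  expect_equal(tab$form[1], "actual")
  expect_equal(unname(unlist(tab[1, d$name])), d$BP)
  m1lin <- tab[tab$index == "M1" & tab$form == "linear", ]
  expect_equal(round(m1lin[["Cabozantinib"]], 1), 697.3)

  # noiseless synthetic records: predicted equals actual everywhere
  syn <- data.frame(name = paste0("m", 1:8), M1 = c(1:8) * 10)
  syn$Y <- 2 + 0.3 * syn$M1
  stab <- prediction_table(syn, "Y", indices = "M1")
  expect_equal(unname(unlist(stab[2, syn$name])), syn$Y, tolerance = 1e-10)

  expect_error(prediction_table(d, "nope"), "unknown property")
})
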