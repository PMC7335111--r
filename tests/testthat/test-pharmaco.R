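test_that("viability smoothing removes points only when both conditions hold", {
  df <- data.frame(drug = "d1", cell = sprintf("c%d", 1:5), conc_um = 1,
                   viability = c(0.9, 1.0, 1.0, 1.1, 2.4))
  out <- smooth_viability(df)
  # Q3 = 1.1, IQR = 0.1, threshold 1.4; 2.4 > 1.5 and > 1.4 -> removed
  expect_equal(out$retained, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  # 1.4 fails the > 1.5 condition even when far beyond Q3 + 3 IQR
  df2 <- df; df2$viability <- c(1.0, 1.0, 1.0, 1.0, 1.4)
  expect_true(all(smooth_viability(df2)$retained))

  # high value but within Q3 + 3 IQR of a dispersed stratum is kept
  df3 <- df; df3$viability <- c(0.2, 0.8, 1.6, 2.2, 2.6)
  expect_true(all(smooth_viability(df3)$retained))

  # small stratum: IQR rule cannot fire, point kept and flagged
  df4 <- data.frame(drug = "d1", cell = sprintf("c%d", 1:3), conc_um = 1,
                    viability = c(0.9, 1.0, 9.9))
  out4 <- smooth_viability(df4)
  expect_true(all(out4$retained))
  expect_true(all(out4$small_stratum))

  # a pair with no retained point anywhere is dropped
  df5 <- rbind(
    data.frame(drug = "d1", cell = sprintf("c%d", 1:5), conc_um = 1,
               viability = c(1, 1, 1, 1.05, 3)),
    data.frame(drug = "d1", cell = sprintf("c%d", 1:5), conc_um = 10,
               viability = c(1, 1, 1, 1.05, 3)))
  out5 <- smooth_viability(df5)
  expect_equal(attr(out5, "dropped_pairs"), "d1.c5")
  expect_true(all(!out5$retained[df5$cell == "c5"]))
})

test_that("an outlier-free synthetic screen has no removals and injected outliers are caught", {
  clean <- generate_dose_response(drug_screen_config(outlier_rate = 0,
                                                     seed = 6))
  expect_true(all(smooth_viability(clean$data)$retained))

  dirty <- generate_dose_response(drug_screen_config(outlier_rate = 0.05,
                                                     seed = 6))
  sm <- smooth_viability(dirty$data)
  expect_gte(mean(!sm$retained[dirty$data$is_outlier]), 0.95)
  expect_lte(mean(!sm$retained[!dirty$data$is_outlier]), 0.01)
})

test_that("normalized trapezoidal AUC has the stated fixed points and monotonicity", {
  grid <- 10^seq(-2, 1.3, length.out = 7)
  expect_equal(auc_trapezoid(grid, rep(1, 7)), 1)
  expect_equal(auc_trapezoid(grid, rep(0, 7)), 0)
  lin <- seq(1, 0, length.out = 7)      # linear in log-dose -> area 1/2
  expect_equal(auc_trapezoid(grid, lin), 0.5)
  set.seed(13)
  for (i in 1:10) {
    v <- runif(7)
    lower <- v - runif(7, 0, 0.2)
    expect_lte(auc_trapezoid(grid, lower), auc_trapezoid(grid, v))
  }
  expect_warning(a1 <- auc_trapezoid(grid[1], 1), "fewer than two")
  expect_true(is.na(a1))
})

test_that("4PL fitting recovers noiseless truth and applies the top-dose ED50 cap", {
  grid <- 10^seq(log10(0.005), log10(20), length.out = 7)
  f <- function(x, b, c, d, e) c + (d - c) / (1 + exp(b * (log(x) - log(e))))
  fit <- fit_4pl(grid, f(grid, 1, 0, 1, 1), max_dose = 20)
  expect_equal(unname(fit$params["e"]), 1, tolerance = 1e-3)
  expect_equal(fit$status, "ok")
  expect_equal(fit$ed50_assigned, fit$ed50_um)

  # inflection above the top dose: assigned ED50 = highest tested dose
  capped <- fit_4pl(grid, f(grid, 1, 0, 1, 200), max_dose = 20)
  expect_equal(capped$status, "capped")
  expect_equal(capped$ed50_assigned, 20)

  # degenerate all-zero curve: no error, cap still respected
  flat <- fit_4pl(grid, rep(0, 7), max_dose = 20)
  expect_lte(flat$ed50_assigned, 20)
  expect_error(fit_4pl(c(-1, 1, 2, 3), c(1, 1, 0, 0)), "positive")
  short <- fit_4pl(grid[1:3], c(1, 0.5, 0))
  expect_equal(short$status, "failed")
  expect_equal(short$ed50_assigned, 20)
})

test_that("ED50 recovery from noisy curves tracks the truth within the grid's information limit", {
  # 7 doses at viability noise sd 0.05 support ED50 to roughly 10% relative
  # error (fits started at the true parameters do no better); the estimator
  # must sit at that limit and never exceed the top-dose cap
  cfg <- drug_screen_config(n_drugs = 10, n_cells = 10, noise_sd = 0.05,
                            seed = 17)
  sim <- generate_dose_response(cfg)
  sm <- smooth_viability(sim$data)
  fits <- summarize_dose_response(sm, max_dose = 20)
  truth <- sim$truth
  key <- paste(fits$drug, fits$cell)
  e_true <- truth$e[match(key, paste(truth$drug, truth$cell))]
  rel_err <- abs(fits$ed50_um - e_true) / e_true
  expect_lt(median(rel_err, na.rm = TRUE), 0.2)
  expect_true(all(fits$status != "failed"))
  expect_true(all(fits$ed50_assigned <= 20))
})

test_that("subtype selectivity flags planted shifts with the correct direction", {
  set.seed(23)
  labels <- setNames(rep(c("GPC1", "GPC2"), each = 10), sprintf("PDC%02d", 1:20))
  auc <- c(rnorm(10, 0.4, 0.05), rnorm(10, 0.7, 0.05))   # GPC1 sensitive
  summaries <- data.frame(drug = "dA", cell = names(labels), auc = auc,
                          ed50_assigned = auc * 10)
  res <- subtype_selectivity(summaries, labels)
  expect_true(all(res$p < 0.05))
  expect_true(all(res$sensitive_subtype == "GPC1"))

  # identical constant responses: KS p = 1
  summaries$auc <- 0.5; summaries$ed50_assigned <- 5
  res2 <- subtype_selectivity(summaries, labels)
  expect_true(all(res2$p == 1))

  # small groups are skipped
  res3 <- subtype_selectivity(summaries[c(1:2, 11:12), ],
                              labels[c(1:2, 11:12)])
  expect_equal(nrow(res3), 0)
})

test_that("biomarker correlations match Spearman with ties and respect the sharing minimum", {
  cells <- sprintf("PDC%02d", 1:8)
  summaries <- data.frame(drug = "dA", cell = cells,
                          auc = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
                          ed50_assigned = 1:8)
  feat <- rbind(anti = -(1:8), tied = c(1, 1, 2, 2, 3, 3, 4, 4))
  colnames(feat) <- cells
  res <- biomarker_correlation(feat, summaries, metrics = "auc")
  expect_equal(res$rho[res$feature == "anti"], -1)
  hand <- suppressWarnings(cor.test(c(1, 1, 2, 2, 3, 3, 4, 4), 1:8,
                                    method = "spearman"))
  expect_equal(res$rho[res$feature == "tied"], unname(hand$estimate))
  expect_equal(res$p[res$feature == "tied"], hand$p.value)
  few <- biomarker_correlation(feat[, 1:4], summaries[1:4, ], metrics = "auc")
  expect_equal(nrow(few), 0)
})
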