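test_that("background correction subtracts medians and drops non-positive", {
  spots <- make_spots(c("p1", "p2", "p3"),
                      fg_ch1 = c(500, 90, 200), bg_ch1 = c(100, 100, 200),
                      fg_ch2 = c(400, 400, 400), bg_ch2 = c(100, 100, 100))
  long <- suppressMessages(background_correct(spots))
  ch1 <- long[long$dye == "ch1", ]
  expect_equal(ch1$signal[ch1$probe_id == "p1"], 400)
  expect_true(is.na(ch1$signal[ch1$probe_id == "p2"]))   # 90 - 100
  expect_true(is.na(ch1$signal[ch1$probe_id == "p3"]))   # exactly 0
  expect_message(background_correct(spots), "2 non-positive")
})

test_that("array/dye model residuals equal within-cell centred values", {
  design <- make_design()
  cd <- design[order(design$array_id, design$dye), ]
  arrays <- unique(cd$array_id)

  # exactly additive array + dye structure, zero noise -> residuals 0
  set.seed(4)
  a_eff <- stats::setNames(rnorm(length(arrays)), arrays)
  d_eff <- c(ch1 = 0.4, ch2 = -0.4)
  gene_base <- rnorm(30, 9)
  long <- do.call(rbind, lapply(seq_len(nrow(cd)), function(i) {
    data.frame(array_id = cd$array_id[i], dye = cd$dye[i],
               probe_id = sprintf("g%02d", seq_along(gene_base)),
               signal = 2^(gene_base + a_eff[cd$array_id[i]] +
                             d_eff[cd$dye[i]]),
               stringsAsFactors = FALSE)
  }))
  fit <- fit_array_dye_model(long, design)
  centered <- sweep(fit$residuals, 1, rowMeans(fit$residuals), "-")
  expect_lt(max(abs(centered)), 1e-9)

  # cell values {10, 20} -> residuals {-5, +5} (raw scale)
  two <- long[long$probe_id %in% c("g01", "g02"), ]
  two$signal <- rep(c(10, 20), times = nrow(two) / 2)
  fit2 <- fit_array_dye_model(two, design, model_scale = "raw")
  expect_true(all(abs(abs(fit2$residuals) - 5) < 1e-12))

  # cell with < 2 genes errors
  one <- long[long$probe_id == "g01", ]
  expect_error(fit_array_dye_model(one, design), "< 2 genes")
})

test_that("array/dye fit matches the closed-form OLS oracle", {
  design <- make_design()
  set.seed(8)
  n_gene <- 120
  sim <- simulate_experiment(sim_params(n_genes = max(50, n_gene), seed = 8,
                                        qc_spec = list(
                                          aln_frac = c(Ag = 1, Sn = 1),
                                          snr_fail_frac = 0,
                                          flagged_frac = 0)))
  long <- background_correct(sim$spots)
  fit <- fit_array_dye_model(long, sim$design)

  # oracle: lm() with the saturated array*dye factor model on long data
  long$y <- log2(long$signal)
  long$cell <- interaction(long$array_id, long$dye)
  ols <- stats::lm(y ~ 0 + cell, data = long)
  cellmeans <- stats::setNames(stats::coef(ols),
                               sub("^cell", "", names(stats::coef(ols))))
  key <- paste(long$array_id, long$dye, sep = ".")
  oracle_resid <- long$y - cellmeans[key]
  got <- fit$residuals[cbind(match(long$probe_id, rownames(fit$residuals)),
                             match(key, colnames(fit$residuals)))]
  expect_lt(max(abs(got - oracle_resid), na.rm = TRUE), 1e-9)
})

test_that("positivity adjustment shifts by global minimum plus delta", {
  design <- make_design()
  m <- matrix(rnorm(50 * 64), 50, 50 + 14)
  m[1, 1] <- -2; m[1, 2] <- 0; m[1, 3] <- 3
  fit <- structure(list(residuals = m,
                        col_design = hetarray:::.col_design(design),
                        model_scale = "log2"),
                   class = "array_dye_fit")
  adj <- adjust_residuals_positive(fit, delta = 1)
  expect_equal(min(adj$values), 1)
  expect_equal(adj$values - m, matrix(adj$shift, nrow(m), ncol(m)),
               ignore_attr = TRUE)
  # rank preservation / shift equivariance
  expect_equal(order(adj$values[, 1]), order(m[, 1]))
  fit$residuals <- m + 5
  adj2 <- adjust_residuals_positive(fit, delta = 1)
  expect_equal(adj2$values, adj$values, ignore_attr = TRUE)

  # all residuals equal c -> all values = delta
  fit$residuals <- matrix(3.7, 50, 64)
  expect_true(all(adjust_residuals_positive(fit, 1)$values == 1))
  expect_error(adjust_residuals_positive(fit, 0), "positive")
})

test_that("factor ratios are oriented, antisymmetric and intensity-tagged", {
  design <- make_design()
  cd <- hetarray:::.col_design(design)
  codes <- design_codes(design)
  v <- matrix(5, 3, nrow(cd), dimnames = list(c("g1", "g2", "g3"), NULL))
  v[1, codes$species > 0] <- 8   # Ag mean 8, Sn mean 2
  v[1, codes$species < 0] <- 2
  adj <- adjusted_residuals(v, design)
  rs <- compute_factor_log_ratios(adj, "species")
  expect_equal(rs$log2_ratio[rs$probe_id == "g1"], 2)   # log2(8/2)
  expect_equal(rs$log2_ratio[rs$probe_id == "g2"], 0)
  expect_equal(rs$log10_intensity[rs$probe_id == "g1"], log10(5))

  # swapping the level orientation negates every ratio
  v_sw <- v
  v_sw[, codes$species > 0] <- v[, codes$species < 0]
  v_sw[, codes$species < 0] <- v[, codes$species > 0]
  rs_sw <- compute_factor_log_ratios(adjusted_residuals(v_sw, design),
                                     "species")
  expect_equal(rs_sw$log2_ratio, -rs$log2_ratio)

  # genes with no data at one level are dropped
  v_na <- v
  v_na[2, codes$water > 0] <- NA
  rs_na <- compute_factor_log_ratios(adjusted_residuals(v_na, design),
                                     "water")
  expect_false("g2" %in% rs_na$probe_id)

  # single observed level errors
  d1 <- design
  d1$water <- "watered"
  expect_error(compute_factor_log_ratios(adjusted_residuals(v, d1), "water"),
               "single observed level")
})

test_that("loess correction removes a smooth trend and little else", {
  set.seed(9)
  n <- 2000
  intensity <- runif(n, 1, 4)
  truth <- rnorm(n, 0, 0.3)
  bias <- 0.5 * sin(intensity)
  rs <- structure(
    data.frame(probe_id = paste0("g", 1:n), log2_ratio = truth + bias,
               log10_intensity = intensity),
    factor = "water", levels = c("watered", "drought"),
    loess_corrected = FALSE, class = c("factor_ratio_set", "data.frame"))
  out <- loess_correct_ratios(rs, span = 0.4)
  expect_true(attr(out, "loess_corrected"))
  expect_lt(sqrt(mean((out$log2_ratio - truth)^2)), 0.05)

  # already flat: the correction changes little (RMS change below
  # 0.05 * SD of the ratios; the pointwise max is noise-bound at this span)
  rs$log2_ratio <- truth
  flat <- loess_correct_ratios(rs, span = 0.4)
  expect_lt(sqrt(mean((flat$log2_ratio - truth)^2)), 0.05 * sd(truth))

  # constant offset is absorbed
  rs$log2_ratio <- truth + 3
  cent <- loess_correct_ratios(rs, span = 0.4)
  expect_lt(abs(mean(cent$log2_ratio)), 0.05)

  expect_error(loess_correct_ratios(rs[1:10, ], span = 0.4), ">= 20 genes")
})

test_that("dye-swap relabelling leaves adjusted residuals invariant", {
  # zero noise: exchanging the dye labels of every channel changes only
  # the fitted dye effect, not the residuals
  params <- sim_params(n_genes = 60, seed = 15, noise_sd = 0,
                       curved_dye_bias = 0,
                       qc_spec = list(aln_frac = c(Ag = 1, Sn = 1),
                                      snr_fail_frac = 0, flagged_frac = 0))
  sim <- simulate_experiment(params)
  long <- background_correct(sim$spots)
  fit <- fit_array_dye_model(long, sim$design)

  swapped <- sim$design
  swapped$dye <- ifelse(swapped$dye == "ch1", "ch2", "ch1")
  long_sw <- long
  long_sw$dye <- ifelse(long_sw$dye == "ch1", "ch2", "ch1")
  fit_sw <- fit_array_dye_model(long_sw, swapped)

  # same (array, sample) measurement keeps its residual
  r1 <- adjust_residuals_positive(fit)$values
  r2 <- adjust_residuals_positive(fit_sw)$values
  map <- match(paste(fit$col_design$array_id, fit$col_design$sample_id),
               paste(fit_sw$col_design$array_id, fit_sw$col_design$sample_id))
  expect_lt(max(abs(r1 - r2[, map]), na.rm = TRUE), 1e-9)
})
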