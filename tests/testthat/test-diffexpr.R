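test_that("overall pooled model detects a planted common species shift", {
  design <- make_design()
  codes <- design_codes(design)
  set.seed(2)
  n <- 400
  base <- matrix(rnorm(n * 64, 0, 0.1), n, 64)
  shift <- matrix(rep(0.5 * codes$species, each = n), n, 64)  # Delta = 1
  adj <- make_adjusted(base + shift + 10)
  res <- fit_overall_model(adj)
  expect_lt(res$p_value[res$term == "species"], 1e-6)
  expect_gt(min(res$p_value[res$term != "species"]), 1e-4)

  # balanced design, zero noise, no effects -> all F = 0
  res0 <- fit_overall_model(make_adjusted(matrix(7, n, 64)))
  expect_true(all(res0$statistic == 0))

  # a factor stuck at one level is reported as aliased
  d1 <- design
  d1$date <- "day4"
  expect_error(fit_overall_model(make_adjusted(base + 10, design = d1)),
               "aliased.*date")
})

test_that("overall model type-I error is near nominal under the null", {
  design <- make_design()
  set.seed(3)
  reps <- 500
  rej <- matrix(NA, reps, 7)
  for (r in seq_len(reps)) {
    adj <- make_adjusted(matrix(rnorm(50 * 64), 50, 64) + 10)
    res <- fit_overall_model(adj)
    rej[r, ] <- res$p_value < 0.05
  }
  rate <- colMeans(rej)
  # 3 MC-SE band around alpha, jointly over the 7 terms
  band <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_true(all(rate >= 0.05 - band & rate <= 0.05 + band),
              info = paste(round(rate, 3), collapse = ", "))
})

test_that("per-gene estimates equal factor log2 ratios in the exact limit", {
  design <- make_design()
  codes <- design_codes(design)
  # gene depends multiplicatively on water only; raw-scale container so the
  # response is log2 of the values, matching the ratio path exactly
  v <- matrix(2^(5 + 1 * codes$water), 1, 64,
              dimnames = list("g1", NULL))
  adj <- make_adjusted(v, model_scale = "raw")
  res <- fit_per_gene_models(adj)
  est <- res$estimate[res$term == "water" & res$probe_id == "g1"]
  rs <- compute_factor_log_ratios(adj, "water")
  expect_equal(est, rs$log2_ratio[rs$probe_id == "g1"], tolerance = 1e-6)
  expect_equal(est, 2, tolerance = 1e-9)
})

test_that("terms are fitted only when the data can estimate them", {
  design <- make_design()
  codes <- design_codes(design)
  v <- matrix(rnorm(2 * 64) + 10, 2, 64, dimnames = list(c("g1", "g2"), NULL))
  v[1, codes$species < 0] <- NA            # g1 observed in Ag only
  res <- suppressMessages(fit_per_gene_models(make_adjusted(v)))
  g1 <- res[res$probe_id == "g1", ]
  expect_false("species" %in% g1$term)
  expect_false(any(grepl("species:", g1$term)))
  expect_setequal(intersect(g1$term, c("water", "temperature", "date")),
                  c("water", "temperature", "date"))
  g2 <- res[res$probe_id == "g2", ]
  expect_setequal(g2$term, c("species", "water", "temperature", "date",
                             "species:water", "species:temperature",
                             "water:temperature"))

  # zero-noise gene with no effects: estimates 0, p = 1
  v0 <- matrix(4, 1, 64, dimnames = list("flat", NULL))
  r0 <- fit_per_gene_models(make_adjusted(v0))
  expect_true(all(r0$estimate == 0))
  expect_true(all(r0$p_raw == 1))
})

test_that("planted per-gene effects are recovered with high power", {
  design <- make_design()
  codes <- design_codes(design)
  set.seed(6)
  n <- 100
  Y <- matrix(rnorm(n * 64, 0, 0.2), n, 64,
              dimnames = list(sprintf("g%03d", 1:n), NULL))
  Y <- Y + matrix(rep(codes$water, each = n), n, 64)  # +2 watered - drought
  res <- fit_per_gene_models(make_adjusted(Y + 10))
  w <- res[res$term == "water", ]
  expect_gte(mean(w$estimate > 1.5 & w$estimate < 2.5 & w$p_raw < 1e-3),
             0.95)
})

test_that("bonferroni adjustment is per term over fitted genes", {
  res <- structure(
    data.frame(probe_id = c(paste0("g", 1:100), "h1"),
               term = c(rep("water", 100), "date"),
               n_obs = 64,
               estimate = 0,
               p_raw = c(0.001, 0.02, runif(98, 0.2, 1), 0.03)),
    class = c("gene_test_results", "data.frame"))
  adj <- bonferroni_adjust(res)
  expect_equal(adj$p_adj[1], 0.1)    # 0.001 * 100
  expect_equal(adj$p_adj[2], 1)      # 0.02 * 100 capped
  expect_equal(adj$p_adj[101], 0.03) # m = 1 identity
  res$p_raw[1] <- 1.5
  expect_error(bonferroni_adjust(res), "outside")
})

test_that("DE calls follow the |LFC| > 1 and adjusted p < 0.05 rule", {
  res <- structure(
    data.frame(probe_id = c("a", "b", "c", "d"), term = "species",
               n_obs = 64, estimate = c(1.2, 0.9, -3.56, 1.2),
               p_raw = c(0.001, 1e-5, 1e-4, 0.04),
               p_adj = c(0.01, 0.001, 0.01, 0.2)),
    class = c("gene_test_results", "data.frame"))
  out <- call_de(res)
  expect_equal(out$call, c("up", "ns", "down", "ns"))
  s <- de_summary(out)
  expect_equal(s$n_up, 1)
  expect_equal(s$n_down, 1)
  expect_equal(s$n_tested, 4)
  expect_error(call_de(res[, setdiff(names(res), "p_adj")]), "p_adj")
})

test_that("duplicating a gene leaves other raw p-values unchanged", {
  design <- make_design()
  set.seed(10)
  Y <- matrix(rnorm(20 * 64) + 10, 20, 64,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  r1 <- bonferroni_adjust(fit_per_gene_models(make_adjusted(Y)))
  Y2 <- rbind(Y, g99 = Y[1, ])
  r2 <- bonferroni_adjust(fit_per_gene_models(make_adjusted(Y2)))
  w1 <- r1[r1$term == "water" & r1$probe_id != "g99", ]
  w2 <- r2[r2$term == "water" & r2$probe_id != "g99", ]
  expect_equal(w2$p_raw[match(w1$probe_id, w2$probe_id)], w1$p_raw)
  # m grew by one: adjusted p scales 21/20
  expect_equal(w2$p_adj[match(w1$probe_id, w2$probe_id)],
               pmin(1, w1$p_adj * 21 / 20))
})
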