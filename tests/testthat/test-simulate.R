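test_that("the simulated design reproduces the stated experiment shape", {
  sim <- simulate_experiment(sim_params(n_genes = 50, seed = 2))
  d <- sim$design
  expect_equal(length(unique(d$sample_id)), 32)
  by_sp <- table(unique(d[, c("sample_id", "species")])$species)
  expect_equal(as.vector(by_sp[c("Ag", "Sn")]), c(16L, 16L))
  # eight hybridizations (arrays) per species per sampling date
  arr <- unique(d[, c("array_id", "species", "date")])
  expect_true(all(table(arr$species, arr$date) == 8))
  # every array is part of a dye-swap pair
  pairs <- dye_swap_pairs(d)
  expect_equal(nrow(pairs), 16)
  expect_setequal(c(pairs$array_1, pairs$array_2), unique(d$array_id))
  # each sample measured once per dye
  expect_true(all(table(d$sample_id, d$dye) == 1))
})

test_that("the generator is byte-reproducible from its seed", {
  p <- sim_params(n_genes = 60, seed = 31)
  s1 <- simulate_experiment(p)
  s2 <- simulate_experiment(p)
  expect_identical(s1, s2)
  expect_identical(simulate_alignments(p), simulate_alignments(p))
  expect_identical(simulate_annotations(p), simulate_annotations(p))
  s3 <- simulate_experiment(sim_params(n_genes = 60, seed = 32))
  expect_false(identical(s1$spots, s3$spots))
})

test_that("alignment planting is exact-count, including the extremes", {
  base <- list(snr_fail_frac = 0, flagged_frac = 0)
  for (frac in c(0, 0.6, 1)) {
    p <- sim_params(n_genes = 100, seed = 33,
                    qc_spec = c(list(aln_frac = c(Ag = frac, Sn = 0.5)),
                                base))
    hits <- simulate_alignments(p)
    sets <- filter_by_alignment(hits, qc_config())
    n_ag <- if ("Ag" %in% names(sets)) length(sets$Ag) else 0
    expect_equal(n_ag, round(frac * 100))
    expect_equal(length(sets$Sn), 50)
    expect_equal(sets$Ag, attr(hits, "included")$Ag)
  }
})

test_that("annotations carry the planted length bias and enrichment", {
  p <- sim_params(n_genes = 800, seed = 34)
  ann <- simulate_annotations(p)
  lens <- ann$map$lengths
  expect_true(all(lens >= 100 & lens <= 3000))
  expect_equal(length(lens), 800)
  # planted construction: enriched members have boosted DE odds, and the
  # length-confounded members sit where the bias elevates expected DE
  # (asserted on the expected probabilities, not one noisy realization)
  p_de <- ann$truth$p_de
  k <- ann$truth$enrich_odds
  enr <- ann$map$categories$probe_id[ann$map$categories$category ==
                                       ann$truth$enriched]
  p_boost <- p_de[enr] * k / (1 - p_de[enr] + k * p_de[enr])
  expect_gt(mean(p_boost), mean(p_de))
  conf <- ann$map$categories$probe_id[ann$map$categories$category ==
                                        ann$truth$confounded]
  expect_true(all(lens[conf] >= quantile(lens, 0.6)))
  expect_gt(mean(p_de[conf]), mean(p_de))
})

test_that("simulated artifacts round-trip through the package readers", {
  p <- sim_params(n_genes = 50, seed = 35)
  sim <- simulate_experiment(p)
  dir <- withr::local_tempdir()
  write_spot_table(sim$spots, file.path(dir, "spots.tsv"))
  write_design_table(sim$design, file.path(dir, "design.tsv"))
  spots <- read_spot_table(file.path(dir, "spots.tsv"))
  expect_equal(spots$probe_id, sim$spots$probe_id)
  expect_equal(spots$fg_ch1, sim$spots$fg_ch1, tolerance = 1e-12)
  design <- read_design_table(file.path(dir, "design.tsv"))
  expect_identical(design, sim$design)

  hits <- simulate_alignments(p)
  write_alignment_table(hits[hits$species_db == "Ag", ],
                        file.path(dir, "aln_ag.tsv"))
  back <- read_alignment_table(file.path(dir, "aln_ag.tsv"), "Ag")
  expect_equal(back$qseqid, hits$qseqid[hits$species_db == "Ag"])
  expect_equal(back$evalue, hits$evalue[hits$species_db == "Ag"],
               tolerance = 1e-12)

  ann <- simulate_annotations(p)
  write_probe_fasta(ann$map$lengths, file.path(dir, "probes.fa"))
  .write_tsv <- function(x, f) utils::write.table(
    x, f, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_tsv(ann$map$categories, file.path(dir, "go.tsv"))
  map <- read_annotation_map(file.path(dir, "go.tsv"),
                             file.path(dir, "probes.fa"))
  expect_equal(map$lengths[names(ann$map$lengths)], ann$map$lengths)
})

test_that("parameter validation rejects out-of-range worlds", {
  expect_error(sim_params(n_genes = 10), ">= 50")
  expect_error(sim_params(noise_sd = -1), ">= 0")
  expect_error(sim_params(qc_spec = list(aln_frac = c(Ag = 1.5, Sn = 0.5),
                                         snr_fail_frac = 0,
                                         flagged_frac = 0)),
               "fractions")
})

test_that("end to end: the pipeline recovers the planted world", {
  # the headline regression test: default effects |2| at sigma 0.3
  res <- run_sim_pipeline(sim_params(n_genes = 500, seed = 36))
  de <- res$de
  for (tm in c("species", "water", "temperature", "date")) {
    r <- de[de$term == tm, ]
    truth <- res$sim$truth$effects[r$probe_id, tm]
    planted <- truth != 0
    expect_gt(sum(planted), 5)
    expect_gte(mean(r$call[planted] != "ns"), 0.8)
    expect_lte(mean(r$call[!planted] != "ns"), 0.05)
  }
})
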