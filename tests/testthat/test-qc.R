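test_that("SNR window is inclusive and applies to both channels", {
  spots <- make_spots(
    probe_id = c("boundary", "high", "low", "flagged", "zerobg"),
    fg_ch1 = c(300, 1100, 250, 300, 300),
    bg_ch1 = c(100, 100, 100, 100, 0),
    fg_ch2 = c(300, 300, 300, 300, 300),
    bg_ch2 = c(100, 100, 100, 100, 100),
    flagged = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  kept <- suppressMessages(filter_by_snr(spots, qc_config()))
  expect_equal(kept$probe_id, "boundary")  # SNR exactly 3 is kept
  expect_message(filter_by_snr(spots, qc_config()), "zero background")
})

test_that("alignment filter uses evalue <= 1e-10 and length > 150 strictly", {
  hits <- data.frame(
    qseqid = c("a", "b", "c", "d"),
    sseqid = "t", pident = 99,
    length = c(200, 300, 150, 151),
    mismatch = 0, gapopen = 0, qstart = 1, qend = 1, sstart = 1, send = 1,
    evalue = c(1e-12, 1e-9, 1e-20, 1e-10),
    bitscore = 100, species_db = "Ag", stringsAsFactors = FALSE)
  sets <- filter_by_alignment(hits, qc_config())
  expect_equal(sets$Ag, c("a", "d"))
})

test_that("included sets are the SNR/alignment conjunction by species", {
  design <- data.frame(
    array_id = rep(c("a1", "a2"), each = 2),
    dye = rep(c("ch1", "ch2"), 2),
    sample_id = c("s1", "s2", "s3", "s4"),
    species = rep(c("Ag", "Sn"), each = 2),
    water = "watered", temperature = rep(c("ambient", "heated"), 2),
    date = "day4", replicate = 1L, stringsAsFactors = FALSE)
  # p1 passes SNR on the Ag array only; p2 on both; p3 nowhere
  spots <- rbind(
    make_spots(c("p1", "p2", "p3"), fg_ch1 = c(500, 500, 2000),
               bg_ch1 = 100, fg_ch2 = c(500, 500, 2000), bg_ch2 = 100,
               array_id = "a1"),
    make_spots(c("p1", "p2", "p3"), fg_ch1 = c(2000, 500, 2000),
               bg_ch1 = 100, fg_ch2 = c(500, 500, 2000), bg_ch2 = 100,
               array_id = "a2"))
  aln <- list(Ag = c("p1", "p2", "p3"), Sn = c("p1", "p2", "p3"))
  snr_pass <- suppressMessages(filter_by_snr(spots, qc_config()))
  inc <- build_included_sets(snr_pass, design, aln,
                             universe = c("p1", "p2", "p3"))
  expect_setequal(inc$per_species$Ag, c("p1", "p2"))
  expect_setequal(inc$per_species$Sn, "p2")
  expect_equal(inc$common, "p2")
  # alignment set membership is necessary, not sufficient
  aln2 <- list(Ag = "p3", Sn = character(0))
  inc2 <- build_included_sets(snr_pass, design, aln2,
                              universe = c("p1", "p2", "p3"))
  expect_length(inc2$per_species$Ag, 0)
  expect_error(build_included_sets(snr_pass, design, aln, character(0)),
               "empty probe universe")
})

test_that("widening QC thresholds never shrinks included sets", {
  params <- sim_params(n_genes = 80, seed = 21, bg_model = "gamma")
  sim <- simulate_experiment(params)
  hits <- simulate_alignments(params)
  base <- qc_config()
  wider <- list(qc_config(snr_low = 2, snr_high = 12),
                qc_config(evalue_max = 1e-8),
                qc_config(min_align_len = 100),
                qc_config(snr_low = 1, snr_high = 20, evalue_max = 1e-5,
                          min_align_len = 10))
  get_sets <- function(cfg) {
    suppressMessages(included_sets(sim$spots, sim$design, hits,
                                   cfg))$included$per_species
  }
  s0 <- get_sets(base)
  for (cfg in wider) {
    s1 <- get_sets(cfg)
    for (sp in names(s0)) {
      expect_true(all(s0[[sp]] %in% s1[[sp]]))
    }
  }
})

test_that("included sets match the planted generator counts exactly", {
  params <- sim_params(n_genes = 1000, seed = 13,
                       qc_spec = list(aln_frac = c(Ag = 0.6, Sn = 0.55),
                                      snr_fail_frac = 0,
                                      flagged_frac = 0))
  sim <- simulate_experiment(params)
  hits <- simulate_alignments(params)
  planted <- attr(hits, "included")
  qc <- suppressMessages(included_sets(sim$spots, sim$design, hits,
                                       qc_config()))
  expect_equal(qc$included$per_species$Ag, planted$Ag)
  expect_equal(qc$included$per_species$Sn, planted$Sn)
  expect_equal(length(qc$included$per_species$Ag), 600)
  expect_equal(length(qc$included$per_species$Sn), 550)
  expect_equal(qc$included$common, intersect(planted$Ag, planted$Sn))
  # common set invariant under species processing order
  qc2 <- suppressMessages(
    included_sets(sim$spots, sim$design,
                  hits[order(match(hits$species_db, c("Sn", "Ag"))), ],
                  qc_config()))
  expect_equal(qc2$included$common, qc$included$common)
})
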