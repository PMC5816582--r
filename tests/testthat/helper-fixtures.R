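# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (per-item loops, exhaustive enumeration)
# and never call the code paths they check.

# --- tiny design fixtures ---------------------------------------------------

# the standard 32-sample dye-swap design; deterministic and, importantly,
# does not touch the global RNG stream
make_design <- function(n_replicates = 2) {
  hetarray:::.sim_design(n_replicates)
}

# spot table from explicit vectors (single array by default)
make_spots <- function(probe_id, fg_ch1, bg_ch1, fg_ch2, bg_ch2,
                       flagged = FALSE, array_id = "A1") {
  data.frame(array_id = array_id, probe_id = probe_id,
             fg_ch1 = fg_ch1, bg_ch1 = bg_ch1,
             fg_ch2 = fg_ch2, bg_ch2 = bg_ch2,
             flagged = flagged, stringsAsFactors = FALSE)
}

# adjusted-residual container straight from a matrix, using a standard
# 32-sample design's channel layout
make_adjusted <- function(values, design = make_design(),
                          model_scale = "log2") {
  adjusted_residuals(values, design, model_scale = model_scale)
}

# channel-level +/-1 codes for a design, ordered like the matrix columns
design_codes <- function(design) {
  cd <- design[order(design$array_id, design$dye), ]
  list(
    species = ifelse(cd$species == "Ag", 1, -1),
    water = ifelse(cd$water == "watered", 1, -1),
    temperature = ifelse(cd$temperature == "ambient", 1, -1),
    date = ifelse(cd$date == "day4", 1, -1),
    sample_id = cd$sample_id
  )
}

# --- independent oracles ----------------------------------------------------

# brute-force re-evaluation of both QC criteria, one probe at a time
oracle_included <- function(spots, design, hits, snr_low = 3, snr_high = 10,
                            evalue_max = 1e-10, min_len = 150) {
  species <- sort(unique(design$species))
  out <- list()
  for (sp in species) {
    arrays <- unique(design$array_id[design$species == sp])
    inc <- character(0)
    for (p in unique(spots$probe_id)) {
      snr_ok <- FALSE
      for (a in arrays) {
        row <- spots[spots$probe_id == p & spots$array_id == a, ]
        if (nrow(row) != 1 || row$flagged) next
        if (row$bg_ch1 <= 0 || row$bg_ch2 <= 0) next
        s1 <- row$fg_ch1 / row$bg_ch1
        s2 <- row$fg_ch2 / row$bg_ch2
        if (s1 >= snr_low && s1 <= snr_high &&
            s2 >= snr_low && s2 <= snr_high) {
          snr_ok <- TRUE
          break
        }
      }
      aln_ok <- FALSE
      hp <- hits[hits$qseqid == p & hits$species_db == sp, ]
      for (i in seq_len(nrow(hp))) {
        if (hp$evalue[i] <= evalue_max && hp$length[i] > min_len) {
          aln_ok <- TRUE
          break
        }
      }
      if (snr_ok && aln_ok) inc <- c(inc, p)
    }
    out[[sp]] <- sort(inc)
  }
  out
}

# exact Wallenius pmf by enumeration of all ordered draw sequences
oracle_wallenius_pmf <- function(m1, m2, n, odds) {
  pmf <- numeric(n + 1)
  recurse <- function(r1, r2, draws, x, prob) {
    if (draws == 0) {
      pmf[x + 1] <<- pmf[x + 1] + prob
      return(invisible())
    }
    tot <- odds * r1 + r2
    if (r1 > 0) recurse(r1 - 1, r2, draws - 1, x + 1, prob * odds * r1 / tot)
    if (r2 > 0) recurse(r1, r2 - 1, draws - 1, x, prob * r2 / tot)
  }
  recurse(m1, m2, n, 0, 1)
  pmf
}

# planted-block expression fixture for module detection
sim_blocks <- function(n_noise = 30, block_sizes = c(20, 20), n_samples = 20,
                       within_cor = 0.9, sd_noise = 1) {
  n <- n_noise + sum(block_sizes)
  lambda <- sqrt(within_cor / (1 - within_cor)) * sd_noise
  expr <- matrix(rnorm(n * n_samples, 0, sd_noise), n, n_samples)
  labels <- integer(n)
  offset <- 0
  for (b in seq_along(block_sizes)) {
    z <- rnorm(n_samples)
    idx <- offset + seq_len(block_sizes[b])
    expr[idx, ] <- expr[idx, ] + lambda * matrix(z, block_sizes[b],
                                                 n_samples, byrow = TRUE)
    labels[idx] <- b
    offset <- offset + block_sizes[b]
  }
  rownames(expr) <- sprintf("g%03d", seq_len(n))
  names(labels) <- rownames(expr)
  list(expr = expr, labels = labels)
}

# one simulated experiment run through QC + normalization + per-gene DE
run_sim_pipeline <- function(params) {
  sim <- simulate_experiment(params)
  hits <- simulate_alignments(params)
  qc <- suppressMessages(included_sets(sim$spots, sim$design, hits,
                                       qc_config()))
  keep <- Reduce(union, qc$included$per_species)
  spots_kept <- qc$snr_pass[qc$snr_pass$probe_id %in% keep, ]
  signals <- suppressMessages(background_correct(spots_kept))
  fit <- fit_array_dye_model(signals, sim$design)
  adjusted <- adjust_residuals_positive(fit)
  res <- suppressMessages(fit_per_gene_models(adjusted))
  res <- call_de(bonferroni_adjust(res))
  list(sim = sim, hits = hits, qc = qc, adjusted = adjusted, de = res)
}
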