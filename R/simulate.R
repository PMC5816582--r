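# Synthetic experiment generator.  The stated world mirrors the emulated
# study: 2 species x 2 water x 2 temperature x 2 dates x n_replicates
# samples (32 at the default n_replicates = 2, 16 per species), dye-swapped
# two-color hybridizations pairing heated vs ambient samples (8 per species
# per date), additive array and dye effects, an intensity-dependent curved
# dye bias, planted per-gene treatment effects, planted correlated gene
# modules, length-biased DE probabilities for enrichment, and exact-count
# planted QC inclusion sets.  Everything is reproducible from `seed`.

#' Simulation parameters
#'
#' Defaults are the package's stated world (see the methods vignette):
#' gene baselines N(8.5, 0.8) on log2 scale, array effects SD 0.5, dye
#' effects SD 0.3, curved dye bias amplitude 0.5 (one sine period across
#' the baseline range), observation noise SD 0.3, per-term planted |log2
#' effect| 2 on 5% of genes, two planted 20-gene modules of within-module
#' correlation 0.9, alignment-inclusion fractions 0.614 (Ag) and 0.566
#' (Sn), 5% of probes planted to fail the SNR window everywhere, spot
#' backgrounds Gamma(shape 4, scale 25), and probe lengths
#' LogNormal(6, 0.5) truncated to \[100, 3000\] bp with a logistic length
#' bias on DE probability centred at 500 bp.
#'
#' @param n_genes number of probes (>= 50).
#' @param n_replicates replicates per treatment cell (default 2).
#' @param seed integer seed; every simulated artifact is a deterministic
#'   function of it.
#' @param array_effect_sd,dye_effect_sd SDs of additive array/dye effects
#'   (log2 scale).
#' @param curved_dye_bias amplitude of the intensity-dependent dye bias.
#' @param noise_sd per-observation noise SD (log2 scale).
#' @param baseline_mean,baseline_sd gene baseline log2-intensity
#'   distribution.
#' @param effects named list per main-effect term: `list(size =, frac =,
#'   sign = "both"|"up"|"down")`.
#' @param module_spec list of `list(size =, cor =)` planted modules.
#' @param length_bias `list(midpoint =, scale =)` of the logistic
#'   P(DE | length) curve used for enrichment fixtures.
#' @param qc_spec `list(aln_frac = c(Ag =, Sn =), snr_fail_frac =,
#'   flagged_frac =)`.
#' @param bg_model `"snr_controlled"` (default) derives the background from
#'   the signal and a per-spot SNR target so planted inclusion sets are
#'   exact; `"gamma"` draws backgrounds Gamma(`bg_shape`, `bg_scale`)
#'   independently of signal, making SNR inclusion stochastic.
#' @param snr_range uniform range of per-spot SNR targets for pass-planted
#'   probes (strictly inside the \[3, 10\] window).
#' @param snr_fail_value SNR forced on fail-planted probes.
#' @param bg_shape,bg_scale Gamma parameters of spot background medians
#'   (`bg_model = "gamma"`).
#' @param annotation `list(n_categories =, cat_size =, enrich_odds =)`.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_genes = 1000,
                       n_replicates = 2,
                       seed = 1,
                       array_effect_sd = 0.5,
                       dye_effect_sd = 0.3,
                       curved_dye_bias = 0.5,
                       noise_sd = 0.3,
                       baseline_mean = 8.5,
                       baseline_sd = 0.8,
                       effects = list(
                         species = list(size = 2, frac = 0.05, sign = "both"),
                         water = list(size = 2, frac = 0.05, sign = "both"),
                         temperature = list(size = 2, frac = 0.05, sign = "both"),
                         date = list(size = 2, frac = 0.05, sign = "both")),
                       module_spec = list(list(size = 20, cor = 0.9),
                                          list(size = 20, cor = 0.9)),
                       length_bias = list(midpoint = 700, scale = 400),
                       qc_spec = list(aln_frac = c(Ag = 0.614, Sn = 0.566),
                                      snr_fail_frac = 0.05,
                                      flagged_frac = 0.01),
                       bg_model = c("snr_controlled", "gamma"),
                       snr_range = c(4, 9), snr_fail_value = 15,
                       bg_shape = 4, bg_scale = 25,
                       annotation = list(n_categories = 12, cat_size = 25,
                                         enrich_odds = 4)) {
  bg_model <- match.arg(bg_model)
  if (n_genes < 50) stop_fmt("sim_params: n_genes must be >= 50")
  if (n_replicates < 1) stop_fmt("sim_params: n_replicates must be >= 1")
  sds <- c(array_effect_sd, dye_effect_sd, noise_sd, baseline_sd)
  if (any(sds < 0)) stop_fmt("sim_params: standard deviations must be >= 0")
  fr <- c(qc_spec$aln_frac, qc_spec$snr_fail_frac, qc_spec$flagged_frac,
          vapply(effects, function(e) e$frac, numeric(1)))
  if (any(fr < 0 | fr > 1)) stop_fmt("sim_params: fractions must be in [0, 1]")
  structure(as.list(environment()), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("sim_params: %d genes, %d replicates, seed %d\n",
              x$n_genes, x$n_replicates, x$seed))
  invisible(x)
}

.probe_ids <- function(n) sprintf("P%05d", seq_len(n))

.sim_design <- function(n_replicates) {
  units <- expand.grid(replicate = seq_len(n_replicates),
                       water = .FACTORS$water, date = .FACTORS$date,
                       species = .FACTORS$species,
                       stringsAsFactors = FALSE)
  sample_name <- function(sp, w, tp, d, r) {
    paste(sp, substr(w, 1, 1), substr(tp, 1, 1), d, paste0("r", r), sep = "_")
  }
  rows <- list()
  for (u in seq_len(nrow(units))) {
    sp <- units$species[u]; w <- units$water[u]
    d <- units$date[u]; r <- units$replicate[u]
    s_amb <- sample_name(sp, w, "ambient", d, r)
    s_hot <- sample_name(sp, w, "heated", d, r)
    a1 <- sprintf("A%02d", 2 * u - 1)
    a2 <- sprintf("A%02d", 2 * u)
    mk <- function(arr, dye, sid, tp) {
      data.frame(array_id = arr, dye = dye, sample_id = sid, species = sp,
                 water = w, temperature = tp, date = d, replicate = r,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- rbind(
      mk(a1, "ch1", s_amb, "ambient"), mk(a1, "ch2", s_hot, "heated"),
      mk(a2, "ch1", s_hot, "heated"), mk(a2, "ch2", s_amb, "ambient"))
  }
  validate_design(do.call(rbind, rows))
}

#' Simulate a complete heterologous hybridization experiment
#'
#' Builds the full factorial sample grid, pairs heated-vs-ambient samples
#' on dye-swapped array pairs, and generates spot foreground/background
#' medians as `bg + 2^(baseline + array + dye + planted effects + module
#' latent + curved dye bias + noise)`, together with the ground truth.
#'
#' @param params a [sim_params()] object.
#' @return A list of class `sim_experiment` with `spots` (spot table),
#'   `design` (design table) and `truth` (planted effects matrix, per-term
#'   DE labels, module labels, SNR-fail set, baselines, latent factors).
#' @export
simulate_experiment <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  probes <- .probe_ids(n)
  design <- .sim_design(params$n_replicates)
  cd <- .col_design(design)
  n_col <- nrow(cd)

  baseline <- stats::rnorm(n, params$baseline_mean, params$baseline_sd)
  arrays <- unique(cd$array_id)
  a_eff <- stats::setNames(stats::rnorm(length(arrays),
                                        0, params$array_effect_sd), arrays)
  d_eff <- stats::setNames(stats::rnorm(2, 0, params$dye_effect_sd), .DYES)

  # planted SNR failures (saturation-like) are chosen first so that DE and
  # module planting never lands on probes the QC stage removes by design
  n_fail <- round(params$qc_spec$snr_fail_frac * n)
  fail_idx <- if (n_fail > 0) sample(n, n_fail) else integer(0)
  snr_fail <- probes[fail_idx]
  usable <- setdiff(seq_len(n), fail_idx)

  # planted per-term effects: exact-count planting
  eff <- matrix(0, n, length(.MAIN_TERMS),
                dimnames = list(probes, .MAIN_TERMS))
  de_labels <- list()
  for (tm in .MAIN_TERMS) {
    e <- params$effects[[tm]]
    n_de <- round(e$frac * n)
    idx <- if (n_de > 0) sample(usable, n_de) else integer(0)
    sgn <- switch(e$sign,
                  both = sample(c(-1, 1), n_de, replace = TRUE),
                  up = rep(1, n_de), down = rep(-1, n_de))
    eff[idx, tm] <- e$size * sgn
    de_labels[[tm]] <- stats::setNames(logical(n), probes)
    de_labels[[tm]][idx] <- TRUE
  }

  # planted modules: disjoint gene sets, shared per-sample latent factors
  module_labels <- stats::setNames(integer(n), probes)
  pool <- sample(usable)
  samples <- unique(cd$sample_id)
  latents <- matrix(0, nrow = length(params$module_spec),
                    ncol = length(samples),
                    dimnames = list(NULL, samples))
  lambda <- numeric(length(params$module_spec))
  for (m in seq_along(params$module_spec)) {
    ms <- params$module_spec[[m]]
    idx <- pool[seq_len(ms$size)]
    pool <- pool[-seq_len(ms$size)]
    module_labels[idx] <- m
    latents[m, ] <- stats::rnorm(length(samples))
    # dye-swap duplicates average the noise: per-sample noise SD is
    # noise_sd / sqrt(2), so this lambda yields the target correlation
    lambda[m] <- params$noise_sd / sqrt(2) * sqrt(ms$cor / (1 - ms$cor))
  }

  # log2 signal per (gene, channel)
  code <- function(f) ifelse(cd[[f]] == .FACTORS[[f]][1], 1, -1)
  xmat <- rbind(species = code("species"), water = code("water"),
                temperature = code("temperature"), date = code("date"))
  y <- matrix(baseline, n, n_col) +
       matrix(a_eff[cd$array_id], n, n_col, byrow = TRUE) +
       matrix(d_eff[cd$dye], n, n_col, byrow = TRUE) +
       (eff %*% xmat) / 2 +
       matrix(stats::rnorm(n * n_col, 0, params$noise_sd), n, n_col)
  for (m in seq_along(params$module_spec)) {
    idx <- which(module_labels == m)
    y[idx, ] <- y[idx, ] +
      lambda[m] * matrix(latents[m, cd$sample_id], length(idx), n_col,
                         byrow = TRUE)
  }
  # curved (intensity-dependent) dye bias on channel 2
  brange <- range(baseline)
  bias <- params$curved_dye_bias *
    sin(2 * pi * (baseline - brange[1]) / diff(brange))
  y[, cd$dye == "ch2"] <- y[, cd$dye == "ch2"] + bias

  if (params$bg_model == "snr_controlled") {
    # per-spot SNR target drawn strictly inside the window for pass-planted
    # probes, fixed outside it for fail-planted ones, and the background
    # derived as signal / (SNR - 1): inclusion sets are then exact by
    # construction (signal = fg - bg = 2^y is unchanged)
    tgt <- matrix(stats::runif(n * n_col, params$snr_range[1],
                               params$snr_range[2]), n, n_col)
    if (length(fail_idx)) tgt[fail_idx, ] <- params$snr_fail_value
    bg <- 2^y / (tgt - 1)
    fg <- bg + 2^y
  } else {
    bg <- matrix(stats::rgamma(n * n_col, shape = params$bg_shape,
                               scale = params$bg_scale), n, n_col)
    fg <- bg + 2^y
    if (length(fail_idx)) fg[fail_idx, ] <- params$snr_fail_value * bg[fail_idx, ]
  }

  flagged <- matrix(stats::runif(n * length(arrays)) <
                      params$qc_spec$flagged_frac, n, length(arrays),
                    dimnames = list(probes, arrays))
  spot_list <- lapply(arrays, function(arr) {
    c1 <- which(cd$array_id == arr & cd$dye == "ch1")
    c2 <- which(cd$array_id == arr & cd$dye == "ch2")
    data.frame(array_id = arr, probe_id = probes,
               fg_ch1 = fg[, c1], bg_ch1 = bg[, c1],
               fg_ch2 = fg[, c2], bg_ch2 = bg[, c2],
               flagged = flagged[, arr], stringsAsFactors = FALSE)
  })
  spots <- do.call(rbind, spot_list)
  rownames(spots) <- NULL

  truth <- list(effects = eff, de_labels = de_labels,
                module_labels = module_labels, snr_fail = sort(snr_fail),
                baseline = stats::setNames(baseline, probes),
                array_effects = a_eff, dye_effects = d_eff,
                latents = latents, dye_bias = stats::setNames(bias, probes))
  structure(list(spots = spots, design = design, truth = truth,
                 params = params),
            class = "sim_experiment")
}

#' Simulate cross-species alignment tables
#'
#' Per species, an exact planted fraction of probes receives one
#' qualifying BLAST hit (e-value <= 1e-12, alignment length in 151-400);
#' the remainder receive, at random, either no hit or a disqualifying one
#' (e-value 1e-8, or alignment length <= 150).
#'
#' @param params a [sim_params()] object.
#' @param probe_ids probe universe (default: the ids
#'   [simulate_experiment()] would generate).
#' @return data.frame of outfmt-6 hits with `species_db`; attribute
#'   `included` holds the planted per-species inclusion sets.
#' @export
simulate_alignments <- function(params = sim_params(),
                                probe_ids = .probe_ids(params$n_genes)) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  n <- length(probe_ids)
  all_hits <- list()
  included <- list()
  for (sp in names(params$qc_spec$aln_frac)) {
    k <- round(params$qc_spec$aln_frac[[sp]] * n)
    inc <- if (k > 0) sort(sample(probe_ids, k)) else character(0)
    included[[sp]] <- inc
    rest <- setdiff(probe_ids, inc)
    mk_hit <- function(ids, evalue, len) {
      if (!length(ids)) return(NULL)
      data.frame(qseqid = ids,
                 sseqid = paste0(sp, "_tr", seq_along(ids)),
                 pident = round(stats::runif(length(ids), 85, 100), 1),
                 length = len, mismatch = 0L, gapopen = 0L,
                 qstart = 1L, qend = len, sstart = 1L, send = len,
                 evalue = evalue,
                 bitscore = round(stats::runif(length(ids), 100, 500), 1),
                 species_db = sp, stringsAsFactors = FALSE)
    }
    good <- mk_hit(inc, evalue = 10^-stats::runif(length(inc), 12, 50),
                   len = sample(151:400, length(inc), replace = TRUE))
    # rest: half get a disqualifying hit, half none
    with_bad <- rest[stats::runif(length(rest)) < 0.5]
    bad_by_len <- stats::runif(length(with_bad)) < 0.5
    bad1 <- mk_hit(with_bad[bad_by_len], evalue = 1e-20,
                   len = sample(50:150, sum(bad_by_len), replace = TRUE))
    bad2 <- mk_hit(with_bad[!bad_by_len], evalue = 1e-8,
                   len = sample(151:400, sum(!bad_by_len), replace = TRUE))
    all_hits[[sp]] <- rbind(good, bad1, bad2)
  }
  hits <- do.call(rbind, all_hits)
  rownames(hits) <- NULL
  attr(hits, "included") <- included
  hits
}

#' Simulate annotations, probe lengths and length-biased DE labels
#'
#' Probe lengths are LogNormal(6, 0.5) truncated to \[100, 3000\] bp; DE
#' status follows a logistic length bias `P(DE | len) =
#' plogis((len - midpoint) / scale)`; categories are random draws of
#' `cat_size` probes, plus one planted-enriched category (member DE odds
#' multiplied by `enrich_odds`) and one length-confounded control made of
#' the longest probes.
#'
#' @param params a [sim_params()] object.
#' @param probe_ids probe universe.
#' @param length_biased if `FALSE`, DE is independent of length (the null
#'   configuration); the DE fraction is then the mean of the biased curve.
#' @return list with `map` (an `annotation_map`), `de_status` (named
#'   logical) and `truth` (enriched/confounded category ids and the bias
#'   parameters).
#' @export
simulate_annotations <- function(params = sim_params(),
                                 probe_ids = .probe_ids(params$n_genes),
                                 length_biased = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 2L)
  n <- length(probe_ids)
  lens <- stats::rlnorm(n, meanlog = 6, sdlog = 0.5)
  while (any(bad <- lens < 100 | lens > 3000)) {
    lens[bad] <- stats::rlnorm(sum(bad), meanlog = 6, sdlog = 0.5)
  }
  lens <- stats::setNames(as.integer(round(lens)), probe_ids)
  lb <- params$length_bias
  p_de <- stats::plogis((lens - lb$midpoint) / lb$scale)
  if (!length_biased) p_de <- rep(mean(p_de), n)
  de <- stats::setNames(stats::runif(n) < p_de, probe_ids)

  an <- params$annotation
  cats <- lapply(seq_len(an$n_categories), function(i) {
    data.frame(probe_id = sample(probe_ids, min(an$cat_size, n)),
               category = sprintf("CAT%02d", i), stringsAsFactors = FALSE)
  })
  enr_members <- sample(probe_ids, min(an$cat_size, n))
  # boost DE odds of the enriched category's members by enrich_odds
  p_enr <- p_de[match(enr_members, probe_ids)]
  p_boost <- p_enr * an$enrich_odds / (1 - p_enr + p_enr * an$enrich_odds)
  de[enr_members] <- stats::runif(length(enr_members)) < p_boost
  cats[[length(cats) + 1]] <- data.frame(probe_id = enr_members,
                                         category = "CAT_ENR",
                                         stringsAsFactors = FALSE)
  # length-confounded control: drawn from the upper-middle length range,
  # where DE probability is elevated but not saturated -- the regime in
  # which a mean-odds weighting can actually explain the excess (the very
  # longest probes are DE with probability ~1 under the logistic bias, an
  # excess no per-probe odds summary can fully absorb)
  qs <- stats::quantile(lens, c(0.6, 0.9))
  long_pool <- names(lens)[lens >= qs[1] & lens <= qs[2]]
  long_members <- sample(long_pool, min(an$cat_size, length(long_pool)))
  cats[[length(cats) + 1]] <- data.frame(probe_id = long_members,
                                         category = "CAT_LEN",
                                         stringsAsFactors = FALSE)
  if (all(de) || !any(de)) {
    # degenerate draw (tiny universes): flip one label to keep PWF definable
    de[1] <- !de[1]
  }
  map <- annotation_map(do.call(rbind, cats), lens)
  list(map = map, de_status = de,
       truth = list(enriched = "CAT_ENR", confounded = "CAT_LEN",
                    length_bias = lb, enrich_odds = an$enrich_odds,
                    p_de = stats::setNames(p_de, probe_ids)))
}

#' Write an alignment table in BLAST outfmt-6 layout
#'
#' @param hits alignment hits (the `species_db` column is not written).
#' @param path output path.
#' @export
write_alignment_table <- function(hits, path) {
  utils::write.table(hits[, .OUTFMT6_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a design table
#'
#' @param design design data.frame.
#' @param path output path.
#' @export
write_design_table <- function(design, path) {
  .write_tsv(design[, .DESIGN_COLS], path)
}
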