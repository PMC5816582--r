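# Heterologous-hybridization quality control: a per-channel signal-to-noise
# window and a cross-species alignment filter, combined into per-species
# included-probe sets.

#' QC configuration
#'
#' Defaults are the published thresholds: spots are kept when the
#' signal-to-noise ratio (foreground median / background median, per
#' channel) lies in \[3, 10\] in both channels, and a probe is considered
#' alignable to a species when it has at least one BLASTN hit with
#' e-value <= 1e-10 and alignment length strictly greater than 150 bp.
#'
#' @param snr_low,snr_high inclusive SNR window bounds.
#' @param evalue_max maximum e-value for a qualifying alignment hit.
#' @param min_align_len exclusive lower bound on alignment length (bp).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(snr_low = 3, snr_high = 10, evalue_max = 1e-10,
                      min_align_len = 150) {
  if (!(snr_low > 0 && snr_low < snr_high)) {
    stop_fmt("qc_config: need 0 < snr_low < snr_high")
  }
  if (evalue_max <= 0) stop_fmt("qc_config: evalue_max must be > 0")
  if (min_align_len < 1) stop_fmt("qc_config: min_align_len must be >= 1")
  structure(list(snr_low = snr_low, snr_high = snr_high,
                 evalue_max = evalue_max, min_align_len = min_align_len),
            class = "qc_config")
}

#' @export
print.qc_config <- function(x, ...) {
  cat(sprintf("qc_config: SNR in [%g, %g]; e-value <= %g; length > %g bp\n",
              x$snr_low, x$snr_high, x$evalue_max, x$min_align_len))
  invisible(x)
}

#' Filter spots by the signal-to-noise window
#'
#' SNR is computed per channel as foreground median / background median.
#' A spot is kept only when both channels fall inside the inclusive window
#' `[snr_low, snr_high]`.  Flagged spots are always removed, as are spots
#' with a zero background in either channel (SNR undefined); their counts
#' are reported via `message()`.
#'
#' @param spots data.frame of spot records (see [read_spot_table()]).
#' @param cfg a [qc_config()].
#' @return The surviving subset of `spots` (possibly empty).
#' @export
filter_by_snr <- function(spots, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  n0 <- nrow(spots)
  flagged <- spots$flagged
  zero_bg <- !flagged & (spots$bg_ch1 <= 0 | spots$bg_ch2 <= 0)
  ok <- !flagged & !zero_bg
  snr1 <- spots$fg_ch1 / spots$bg_ch1
  snr2 <- spots$fg_ch2 / spots$bg_ch2
  in_window <- snr1 >= cfg$snr_low & snr1 <= cfg$snr_high &
               snr2 >= cfg$snr_low & snr2 <= cfg$snr_high
  keep <- ok & in_window
  if (any(zero_bg)) {
    message(sprintf("filter_by_snr: %d spot(s) with zero background excluded",
                    sum(zero_bg)))
  }
  message(sprintf("filter_by_snr: kept %d / %d spots (%d flagged removed)",
                  sum(keep), n0, sum(flagged)))
  spots[keep, , drop = FALSE]
}

#' Filter alignment hits into per-species alignable probe sets
#'
#' A probe is retained for a species when it has at least one hit against
#' that species' transcriptome with `evalue <= evalue_max` and
#' `align_length > min_align_len` (strict inequality).
#'
#' @param hits data.frame of alignment hits (see [read_alignment_table()]);
#'   may combine several `species_db` labels.
#' @param cfg a [qc_config()].
#' @return Named list of character vectors of probe ids, one per
#'   `species_db` present in `hits`.
#' @export
filter_by_alignment <- function(hits, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  pass <- hits$evalue <= cfg$evalue_max & hits$length > cfg$min_align_len
  kept <- hits[pass, , drop = FALSE]
  out <- lapply(split(kept$qseqid, kept$species_db), function(p) sort(unique(p)))
  # preserve species with zero survivors
  for (s in setdiff(unique(hits$species_db), names(out))) out[[s]] <- character(0)
  out
}

#' Combine SNR and alignment filters into included-probe sets
#'
#' A probe is included for a species when it passes the SNR window on at
#' least one array hybridized with that species' samples AND belongs to
#' that species' alignable set.  Per-array SNR failures elsewhere become
#' missing values downstream rather than global exclusions.
#'
#' @param snr_pass spot records surviving [filter_by_snr()].
#' @param design validated design table (maps arrays to species).
#' @param aln_sets named list from [filter_by_alignment()].
#' @param universe character vector of all probe ids on the array.
#' @return An object of class `included_sets`: list with `per_species`
#'   (named list of probe-id vectors), `common` (their intersection) and a
#'   `summary` data.frame of counts and fractions of the universe.
#' @export
build_included_sets <- function(snr_pass, design, aln_sets, universe) {
  if (length(universe) == 0) stop_fmt("build_included_sets: empty probe universe")
  design <- validate_design(design)
  array_species <- lapply(split(design$species, design$array_id), unique)
  species <- sort(unique(unlist(array_species)))
  snr_by_species <- lapply(species, function(s) {
    arrays <- names(array_species)[vapply(array_species,
                                          function(v) s %in% v, logical(1))]
    sort(unique(snr_pass$probe_id[snr_pass$array_id %in% arrays]))
  })
  names(snr_by_species) <- species
  per_species <- lapply(species, function(s) {
    aln <- if (s %in% names(aln_sets)) aln_sets[[s]] else character(0)
    intersect(intersect(snr_by_species[[s]], aln), universe)
  })
  names(per_species) <- species
  common <- Reduce(intersect, per_species)
  summary <- data.frame(
    species = c(species, "common"),
    n_included = c(vapply(per_species, length, integer(1)), length(common)),
    fraction = c(vapply(per_species, length, integer(1)),
                 length(common)) / length(universe),
    stringsAsFactors = FALSE
  )
  structure(list(per_species = per_species, common = common,
                 universe_size = length(universe), summary = summary),
            class = "included_sets")
}

#' @export
print.included_sets <- function(x, ...) {
  cat(sprintf("included_sets over a universe of %d probes:\n",
              x$universe_size))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-8s %6d (%.1f%%)\n", x$summary$species[i],
                x$summary$n_included[i], 100 * x$summary$fraction[i]))
  }
  invisible(x)
}

#' One-call QC: run both filters and build the included sets
#'
#' @param spots full spot table (defines the probe universe).
#' @param design validated design table.
#' @param hits combined alignment hits across species databases.
#' @param cfg a [qc_config()].
#' @return A list with `snr_pass` (filtered spots), `aln_sets` and
#'   `included` (the `included_sets` object).
#' @export
included_sets <- function(spots, design, hits, cfg = qc_config()) {
  snr_pass <- filter_by_snr(spots, cfg)
  aln_sets <- filter_by_alignment(hits, cfg)
  inc <- build_included_sets(snr_pass, design, aln_sets,
                             universe = unique(spots$probe_id))
  list(snr_pass = snr_pass, aln_sets = aln_sets, included = inc)
}
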