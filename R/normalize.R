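# Two-stage model-based normalization.  Stage one removes array and dye
# effects with the saturated ANOVA y_ijk = A_i + D_j + (AD)_ij + e_ijk,
# whose residuals (because the interaction saturates the cell structure)
# equal the within-(array, dye)-cell centred values.  Residuals are shifted
# to be strictly positive, then summarised as factor-wise log2 ratios with
# a loess correction against log10 intensity.

#' Background-correct spot intensities
#'
#' Subtracts the median background from the median foreground per channel.
#' Non-positive corrected signals become missing (their count is reported),
#' since they cannot enter a log-scale model.
#'
#' @param spots data.frame of (QC-passed) spot records.
#' @return A long data.frame with columns `array_id`, `dye` (`ch1`/`ch2`),
#'   `probe_id`, `signal` (NA where non-positive).
#' @export
background_correct <- function(spots) {
  long <- rbind(
    data.frame(array_id = spots$array_id, dye = "ch1",
               probe_id = spots$probe_id,
               signal = spots$fg_ch1 - spots$bg_ch1,
               stringsAsFactors = FALSE),
    data.frame(array_id = spots$array_id, dye = "ch2",
               probe_id = spots$probe_id,
               signal = spots$fg_ch2 - spots$bg_ch2,
               stringsAsFactors = FALSE)
  )
  nonpos <- !is.na(long$signal) & long$signal <= 0
  if (any(nonpos)) {
    message(sprintf("background_correct: %d non-positive signal(s) set to missing",
                    sum(nonpos)))
    long$signal[nonpos] <- NA_real_
  }
  long
}

# Column (measurement) design: one row per (array, dye) channel in a fixed
# order; columns of all matrices downstream follow this order.
.col_design <- function(design) {
  design <- validate_design(design)
  cd <- design[order(design$array_id, design$dye), , drop = FALSE]
  cd$column <- paste(cd$array_id, cd$dye, sep = ".")
  rownames(cd) <- NULL
  cd
}

# Long signals -> genes x (array.dye) matrix aligned to the column design.
.signal_matrix <- function(signals, col_design) {
  probes <- sort(unique(signals$probe_id))
  mat <- matrix(NA_real_, nrow = length(probes), ncol = nrow(col_design),
                dimnames = list(probes, col_design$column))
  idx <- cbind(match(signals$probe_id, probes),
               match(paste(signals$array_id, signals$dye, sep = "."),
                     col_design$column))
  keep <- !is.na(idx[, 2])
  mat[idx[keep, , drop = FALSE]] <- signals$signal[keep]
  mat
}

#' Fit the array/dye normalization model
#'
#' Least-squares fit of `y_ijk = mu + A_i + D_j + (AD)_ij + e_ijk` with
#' sum-to-zero effect coding, where `y` is the (by default log2) background-
#' corrected signal of gene `k` on array `i` in channel `j`.  The
#' interaction saturates the (array, dye) cells, so the residual of gene
#' `k` in cell `(i, j)` equals `y_ijk` minus the cell mean; the fit is
#' computed that way and the equivalence with the full OLS fit is part of
#' the test contract.
#'
#' @param signals long data.frame from [background_correct()].
#' @param design validated design table.
#' @param model_scale `"log2"` (default) fits the model on log2 signal;
#'   `"raw"` fits on the fluorescence scale.
#' @return An object of class `array_dye_fit` with the grand mean, array,
#'   dye and interaction effects, the residual matrix (genes x channels)
#'   and the column design.
#' @export
fit_array_dye_model <- function(signals, design,
                                model_scale = c("log2", "raw")) {
  model_scale <- match.arg(model_scale)
  cd <- .col_design(design)
  arrays <- unique(cd$array_id)
  if (length(arrays) < 2) stop_fmt("fit_array_dye_model: need >= 2 arrays")
  y <- .signal_matrix(signals, cd)
  if (model_scale == "log2") y <- log2(y)
  n_per_cell <- colSums(!is.na(y))
  if (any(n_per_cell < 2)) {
    stop_fmt("fit_array_dye_model: cell %s has < 2 genes with data",
             cd$column[which(n_per_cell < 2)[1]])
  }
  cell_means <- colMeans(y, na.rm = TRUE)
  resid <- sweep(y, 2, cell_means, "-")

  # sum-to-zero decomposition of the cell means
  cm <- matrix(cell_means, nrow = length(arrays), ncol = 2, byrow = TRUE,
               dimnames = list(arrays, .DYES))
  grand <- mean(cm)
  a_eff <- rowMeans(cm) - grand
  d_eff <- colMeans(cm) - grand
  ad_eff <- cm - grand - outer(a_eff, rep(1, 2)) - outer(rep(1, length(arrays)), d_eff)

  structure(list(grand_mean = grand, array_effects = a_eff,
                 dye_effects = d_eff, interaction_effects = ad_eff,
                 cell_means = cell_means, residuals = resid,
                 col_design = cd, model_scale = model_scale),
            class = "array_dye_fit")
}

#' @export
print.array_dye_fit <- function(x, ...) {
  cat(sprintf("array_dye_fit (%s scale): %d genes x %d channels on %d arrays\n",
              x$model_scale, nrow(x$residuals), ncol(x$residuals),
              length(x$array_effects)))
  cat(sprintf("  dye effect (ch2 - ch1): %.4g\n",
              x$dye_effects[["ch2"]] - x$dye_effects[["ch1"]]))
  invisible(x)
}

#' Shift residuals to be strictly positive
#'
#' `r' = r - min(r) + delta` over the global residual pool, so that
#' `min(r') = delta > 0` and between-channel contrasts are preserved
#' (the shift is a single global constant).
#'
#' @param fit an `array_dye_fit`.
#' @param delta positive offset added after subtracting the global minimum.
#' @return An object of class `adjusted_residuals`: list with `values`
#'   (genes x channels matrix, all entries >= delta), `col_design`,
#'   `model_scale`, `delta` and the `shift` applied.
#' @export
adjust_residuals_positive <- function(fit, delta = 1.0) {
  stopifnot(inherits(fit, "array_dye_fit"))
  if (!is.finite(delta) || delta <= 0) {
    stop_fmt("adjust_residuals_positive: delta must be a positive number")
  }
  r <- fit$residuals
  if (!any(is.finite(r))) stop_fmt("adjust_residuals_positive: no finite residuals")
  shift <- -min(r, na.rm = TRUE) + delta
  adjusted_residuals(r + shift, fit$col_design,
                     model_scale = fit$model_scale, delta = delta,
                     shift = shift)
}

#' Construct an adjusted-residual container
#'
#' Mostly used by [adjust_residuals_positive()]; exposed so simulations and
#' tests can inject matrices directly.
#'
#' @param values genes x channels numeric matrix (column order must match
#'   `col_design`).
#' @param col_design design table (one row per channel column) or a raw
#'   design table, which will be expanded/ordered via the standard column
#'   ordering.
#' @param model_scale scale the first-stage model was fitted on.
#' @param delta,shift positivity offset bookkeeping.
#' @return An `adjusted_residuals` object.
#' @export
adjusted_residuals <- function(values, col_design,
                               model_scale = c("log2", "raw"),
                               delta = 1.0, shift = NA_real_) {
  model_scale <- match.arg(model_scale)
  if (is.null(col_design$column)) col_design <- .col_design(col_design)
  if (ncol(values) != nrow(col_design)) {
    stop_fmt("adjusted_residuals: %d columns but %d design channels",
             ncol(values), nrow(col_design))
  }
  colnames(values) <- col_design$column
  structure(list(values = values, col_design = col_design,
                 model_scale = model_scale, delta = delta, shift = shift),
            class = "adjusted_residuals")
}

#' @export
print.adjusted_residuals <- function(x, ...) {
  cat(sprintf("adjusted_residuals: %d genes x %d channels (scale %s, delta %g)\n",
              nrow(x$values), ncol(x$values), x$model_scale, x$delta))
  invisible(x)
}

#' Factor-wise log2 expression ratios
#'
#' For one experimental factor, computes per gene the log2 ratio of the
#' arithmetic mean adjusted residual at the first-listed level over the
#' mean at the second-listed level (species: Ag/Sn; water:
#' watered/drought; temperature: ambient/heated; date: day4/day18), and
#' the log10 of the gene's grand-mean adjusted residual as the intensity
#' coordinate.  Genes with no data at either level are dropped.
#'
#' @param adjusted an `adjusted_residuals` object.
#' @param factor one of `"species"`, `"water"`, `"temperature"`, `"date"`.
#' @return An object of class `factor_ratio_set`: data.frame with
#'   `probe_id`, `log2_ratio`, `log10_intensity`; attributes `factor`,
#'   `levels`, `loess_corrected`.
#' @export
compute_factor_log_ratios <- function(adjusted, factor) {
  stopifnot(inherits(adjusted, "adjusted_residuals"))
  factor <- match.arg(factor, names(.FACTORS))
  lv <- .FACTORS[[factor]]
  col_lv <- adjusted$col_design[[factor]]
  observed <- unique(col_lv)
  if (length(intersect(observed, lv)) < 2) {
    stop_fmt("compute_factor_log_ratios: factor %s has a single observed level",
             factor)
  }
  v <- adjusted$values
  m1 <- rowMeans(v[, col_lv == lv[1], drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(v[, col_lv == lv[2], drop = FALSE], na.rm = TRUE)
  grand <- rowMeans(v, na.rm = TRUE)
  ok <- is.finite(m1) & is.finite(m2) & m1 > 0 & m2 > 0
  out <- data.frame(probe_id = rownames(v)[ok],
                    log2_ratio = log2(m1[ok] / m2[ok]),
                    log10_intensity = log10(grand[ok]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, factor = factor, levels = lv, loess_corrected = FALSE,
            class = c("factor_ratio_set", "data.frame"))
}

#' Loess-correct log2 ratios against intensity
#'
#' Removes the intensity-dependent trend (the curved dye bias typical of
#' two-color arrays) by subtracting a degree-1 robust loess fit of the
#' log2 ratio on log10 intensity.
#'
#' @param rs a `factor_ratio_set`.
#' @param span loess span (fraction of points in each local window).
#' @return The ratio set with `log2_ratio` replaced by the corrected values,
#'   the original kept as `log2_ratio_raw` and the loess fit as `loess_fit`;
#'   attribute `loess_corrected` set to `TRUE`.
#' @export
loess_correct_ratios <- function(rs, span = 0.4) {
  stopifnot(inherits(rs, "factor_ratio_set"))
  ok <- is.finite(rs$log2_ratio) & is.finite(rs$log10_intensity)
  if (sum(ok) < 20) {
    stop_fmt("loess_correct_ratios: need >= 20 genes with finite values (have %d)",
             sum(ok))
  }
  fit <- stats::loess(log2_ratio ~ log10_intensity, data = rs[ok, ],
                      span = span, degree = 1, family = "symmetric",
                      surface = "direct")
  trend <- rep(NA_real_, nrow(rs))
  trend[ok] <- stats::predict(fit, newdata = rs$log10_intensity[ok])
  out <- rs
  out$log2_ratio_raw <- rs$log2_ratio
  out$loess_fit <- trend
  out$log2_ratio <- rs$log2_ratio - trend
  attr(out, "loess_corrected") <- TRUE
  attr(out, "span") <- span
  out
}

#' @export
print.factor_ratio_set <- function(x, ...) {
  cat(sprintf("factor_ratio_set (%s: %s / %s), %d genes, loess_corrected = %s\n",
              attr(x, "factor"), attr(x, "levels")[1], attr(x, "levels")[2],
              nrow(x), attr(x, "loess_corrected")))
  invisible(x)
}

#' Average dye-swap duplicate measurements per sample
#'
#' Each sample is measured once per dye on a swap pair of arrays; this
#' collapses the channel-level matrix to a genes x samples matrix by
#' averaging the available measurements of each sample.
#'
#' @param adjusted an `adjusted_residuals` object.
#' @return A genes x samples matrix with an attached `sample_design`
#'   attribute (one row per sample with its factor levels).
#' @export
sample_expression <- function(adjusted) {
  stopifnot(inherits(adjusted, "adjusted_residuals"))
  cd <- adjusted$col_design
  samples <- unique(cd$sample_id)
  out <- vapply(samples, function(s) {
    rowMeans(adjusted$values[, cd$sample_id == s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(adjusted$values)))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- rownames(adjusted$values)
  sd_cols <- c("sample_id", "species", "water", "temperature", "date",
               "replicate")
  sdes <- unique(cd[, sd_cols])
  sdes <- sdes[match(samples, sdes$sample_id), ]
  rownames(sdes) <- NULL
  structure(out, sample_design = sdes)
}
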