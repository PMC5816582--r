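# Second-stage models on the normalized values: one pooled ANOVA across all
# genes for overall factor effects, and per-gene linear models whose
# coefficients are log2 fold changes.  Terms are the four main effects
# (species, water, temperature, date) and the three selected interactions
# (species:water, species:temperature, water:temperature).  Tests are
# Type-II F tests with sum-to-zero (+1/-1) coding; the full-model residual
# variance is the error term.
#
# Response scale: when the first-stage array/dye model was fitted on log2
# signal the adjusted residuals are already log2-scale quantities and are
# used directly; when it was fitted on the raw fluorescence scale the
# response is log2 of the positive-adjusted residuals.

# +1/-1 coded model matrix over the 7 terms, rows following col_design.
.term_matrix <- function(col_design) {
  code <- function(f) ifelse(col_design[[f]] == .FACTORS[[f]][1], 1, -1)
  s <- code("species"); w <- code("water")
  t_ <- code("temperature"); c_ <- code("date")
  X <- cbind(`(Intercept)` = 1, species = s, water = w, temperature = t_,
             date = c_, `species:water` = s * w,
             `species:temperature` = s * t_, `water:temperature` = w * t_)
  X
}

.response_matrix <- function(adjusted) {
  v <- adjusted$values
  if (adjusted$model_scale == "raw") {
    if (any(v[is.finite(v)] <= 0)) {
      stop_fmt("raw-scale response requires strictly positive adjusted residuals")
    }
    v <- log2(v)
  }
  v
}

.term_factors <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# Terms estimable from an observation subset: a main effect needs both
# levels of its factor observed; an interaction needs both levels of both
# parents.  Remaining aliasing (e.g. incomplete cells) is caught by greedy
# column elimination afterwards.
.structural_terms <- function(col_design, obs, terms) {
  two_levels <- vapply(names(.FACTORS), function(f) {
    length(unique(col_design[[f]][obs])) == 2
  }, logical(1))
  keep <- vapply(terms, function(tm) all(two_levels[.term_factors(tm)]),
                 logical(1))
  terms[keep]
}

.rss_mat <- function(Q, Y, y2) {
  # residual sum of squares of each column of Y after projection on span(Q)
  pmax(y2 - colSums(crossprod(Q, Y)^2), 0)
}

#' Fit the pooled overall-effects model
#'
#' ANOVA of the normalized values pooled over all genes on
#' `species + water + temperature + date + species:water +
#' species:temperature + water:temperature`, with sum-to-zero coding and
#' Type-II sums of squares.
#'
#' @param adjusted an `adjusted_residuals` object.
#' @return An object of class `overall_model_result`: data.frame with per-
#'   term `df`, `sumsq`, `statistic` (F), `p_value`, plus attributes
#'   `sigma2` (residual variance) and `df_residual`.
#' @export
fit_overall_model <- function(adjusted) {
  stopifnot(inherits(adjusted, "adjusted_residuals"))
  cd <- adjusted$col_design
  Y <- .response_matrix(adjusted)
  X <- .term_matrix(cd)
  obs_all <- seq_len(nrow(cd))
  aliased <- setdiff(.ALL_TERMS, .structural_terms(cd, obs_all, .ALL_TERMS))
  if (length(aliased)) {
    stop_fmt("fit_overall_model: rank-deficient design; aliased term(s): %s",
             paste(aliased, collapse = ", "))
  }
  # stack (gene, channel) observations
  keep <- !is.na(Y)
  col_idx <- col(Y)[keep]
  y <- Y[keep]
  Xb <- X[col_idx, , drop = FALSE]
  kept_cols <- .keep_columns(Xb)
  dropped <- setdiff(colnames(X), colnames(X)[kept_cols])
  if (length(dropped)) {
    stop_fmt("fit_overall_model: rank-deficient design; aliased term(s): %s",
             paste(dropped, collapse = ", "))
  }
  qr_full <- qr(Xb)
  rss_full <- sum(qr.resid(qr_full, y)^2)
  df_res <- length(y) - ncol(Xb)
  degenerate <- rss_full <= 1e-10 * max(1, sum(y^2))
  sigma2 <- if (degenerate) 0 else rss_full / df_res
  res <- lapply(.ALL_TERMS, function(tm) {
    if (tm %in% .INT_TERMS) {
      base_terms <- setdiff(.ALL_TERMS, tm)
    } else {
      contains <- .INT_TERMS[vapply(.INT_TERMS,
                                    function(i) tm %in% .term_factors(i),
                                    logical(1))]
      base_terms <- setdiff(.ALL_TERMS, c(tm, contains))
    }
    rss_base <- sum(qr.resid(qr(Xb[, c("(Intercept)", base_terms),
                                   drop = FALSE]), y)^2)
    rss_comp <- sum(qr.resid(qr(Xb[, c("(Intercept)", base_terms, tm),
                                   drop = FALSE]), y)^2)
    ss <- max(rss_base - rss_comp, 0)
    f <- if (sigma2 > 0) ss / sigma2 else 0
    p <- if (sigma2 > 0) stats::pf(f, 1, df_res, lower.tail = FALSE) else 1
    data.frame(term = tm, df = 1L, sumsq = ss, statistic = f, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, sigma2 = sigma2, df_residual = df_res,
            class = c("overall_model_result", "data.frame"))
}

#' Fit per-gene linear models
#'
#' For each gene, fits the linear model on that gene's non-missing
#' observations, keeping only the terms estimable from the observed
#' factor-level pattern (e.g. the species term requires data from both
#' species) with at least one residual degree of freedom.  Genes are
#' grouped by missingness pattern and fitted as matrices, so complete
#' designs cost one QR factorization regardless of gene count.
#'
#' Estimates are oriented level-1-minus-level-2 differences on the log2
#' scale for main effects (positive species estimate = higher in
#' A. gerardii) and differences-of-differences for interactions.  Genes
#' with zero residual variance report p = 1.
#'
#' @param adjusted an `adjusted_residuals` object.
#' @param terms character vector of terms to attempt (default all seven).
#' @return An object of class `gene_test_results`: long data.frame with
#'   `probe_id`, `term`, `n_obs`, `estimate`, `p_raw`.
#' @export
fit_per_gene_models <- function(adjusted, terms = .ALL_TERMS) {
  stopifnot(inherits(adjusted, "adjusted_residuals"))
  terms <- match.arg(terms, .ALL_TERMS, several.ok = TRUE)
  cd <- adjusted$col_design
  Y <- t(.response_matrix(adjusted))        # obs x genes
  X <- .term_matrix(cd)
  genes <- colnames(Y)
  obs_mask <- !is.na(Y)
  n_obs_gene <- colSums(obs_mask)
  if (any(n_obs_gene == 0)) {
    message(sprintf("fit_per_gene_models: %d gene(s) with no data dropped",
                    sum(n_obs_gene == 0)))
  }
  pattern <- apply(obs_mask, 2, function(m) paste(which(m), collapse = ","))
  out <- vector("list", 0)
  for (pat in unique(pattern[n_obs_gene > 0])) {
    g_idx <- which(pattern == pat)
    obs <- as.integer(strsplit(pat, ",", fixed = TRUE)[[1]])
    n_obs <- length(obs)
    cand <- .structural_terms(cd, obs, terms)
    if (!length(cand)) next
    Xo <- X[obs, c("(Intercept)", cand), drop = FALSE]
    kept <- .keep_columns(Xo)
    Xk <- Xo[, kept, drop = FALSE]
    fitted_terms <- setdiff(colnames(Xk), "(Intercept)")
    df_res <- n_obs - ncol(Xk)
    if (!length(fitted_terms) || df_res < 1) next
    Yo <- Y[obs, g_idx, drop = FALSE]
    y2 <- colSums(Yo^2)
    qrX <- qr(Xk)
    Qf <- qr.Q(qrX)
    coefs <- qr.coef(qrX, Yo)               # p x genes
    rss_full <- .rss_mat(Qf, Yo, y2)
    sigma2 <- rss_full / df_res
    degenerate <- rss_full <= 1e-10 * pmax(1, y2)
    for (tm in fitted_terms) {
      if (tm %in% .INT_TERMS) {
        base_terms <- setdiff(fitted_terms, tm)
      } else {
        contains <- .INT_TERMS[vapply(.INT_TERMS,
                                      function(i) tm %in% .term_factors(i),
                                      logical(1))]
        base_terms <- setdiff(fitted_terms, c(tm, contains))
      }
      Qb <- qr.Q(qr(Xk[, c("(Intercept)", base_terms), drop = FALSE]))
      Qc <- qr.Q(qr(Xk[, c("(Intercept)", base_terms, tm), drop = FALSE]))
      ss <- pmax(.rss_mat(Qb, Yo, y2) - .rss_mat(Qc, Yo, y2), 0)
      fstat <- ifelse(sigma2 > 0, ss / sigma2, 0)
      p <- ifelse(degenerate, 1,
                  stats::pf(fstat, 1, df_res, lower.tail = FALSE))
      mult <- if (tm %in% .INT_TERMS) 4 else 2
      out[[length(out) + 1]] <- data.frame(
        probe_id = genes[g_idx], term = tm, n_obs = n_obs,
        estimate = mult * coefs[tm, ], p_raw = p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- data.frame(probe_id = character(0), term = character(0),
                      n_obs = integer(0), estimate = numeric(0),
                      p_raw = numeric(0))
  } else {
    res <- do.call(rbind, out)
    res <- res[order(match(res$term, .ALL_TERMS), res$probe_id), ]
  }
  rownames(res) <- NULL
  structure(res, class = c("gene_test_results", "data.frame"))
}

#' Adjust per-gene p-values for multiple testing
#'
#' Bonferroni (default) multiplies each raw p-value by the number of genes
#' for which that term was fitted, per term, capped at 1; `"BH"` applies
#' Benjamini-Hochberg within each term instead.
#'
#' @param results a `gene_test_results` data.frame.
#' @param method `"bonferroni"` or `"BH"`.
#' @return The results with a `p_adj` column added.
#' @export
bonferroni_adjust <- function(results, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (any(results$p_raw < 0 | results$p_raw > 1, na.rm = TRUE)) {
    stop_fmt("bonferroni_adjust: p-values outside [0, 1]")
  }
  results$p_adj <- NA_real_
  for (tm in unique(results$term)) {
    idx <- results$term == tm
    p <- results$p_raw[idx]
    results$p_adj[idx] <- if (method == "bonferroni") {
      pmin(1, length(p) * p)
    } else {
      stats::p.adjust(p, method = "BH")
    }
  }
  results
}

#' Call differential expression
#'
#' A gene is called `up` for a term when its estimate exceeds
#' `lfc_threshold` with adjusted p below `alpha`, `down` for the mirrored
#' condition, and `ns` otherwise (the published rule: |log2 fold change|
#' greater than one at p < 0.05).
#'
#' @param results a `gene_test_results` data.frame with `p_adj` present.
#' @param lfc_threshold strict absolute log2-fold-change threshold.
#' @param alpha strict significance level on the adjusted p-value.
#' @return The results with a `call` column (`up`/`down`/`ns`).
#' @export
call_de <- function(results, lfc_threshold = 1.0, alpha = 0.05) {
  if (is.null(results$p_adj)) {
    stop_fmt("call_de: run bonferroni_adjust() first (no p_adj column)")
  }
  sig <- results$p_adj < alpha
  results$call <- ifelse(sig & results$estimate > lfc_threshold, "up",
                  ifelse(sig & results$estimate < -lfc_threshold, "down",
                         "ns"))
  results
}

#' Per-term differential-expression counts
#'
#' @param results output of [call_de()].
#' @return data.frame with per-term counts of genes tested, up and down.
#' @export
de_summary <- function(results) {
  if (is.null(results$call)) stop_fmt("de_summary: run call_de() first")
  terms <- unique(results$term)
  out <- do.call(rbind, lapply(terms, function(tm) {
    r <- results[results$term == tm, ]
    data.frame(term = tm, n_tested = nrow(r), n_up = sum(r$call == "up"),
               n_down = sum(r$call == "down"),
               n_de = sum(r$call != "ns"), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
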