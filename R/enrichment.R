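# Length-bias-aware category enrichment.  Long probes have more chances to
# be called differentially expressed; the probability weighting function
# (PWF) estimates P(DE | length) by monotone regression, and category
# over/under-representation is tested with the Wallenius noncentral
# hypergeometric distribution using the category's mean weight relative to
# its complement as the draw odds.

# Weighted pool-adjacent-violators: non-decreasing fit to (y, w).
.pava <- function(y, w) {
  n <- length(y)
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      tw <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / tw
      wt[top - 1L] <- tw
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], sz[seq_len(top)])
}

#' Fit the probability weighting function (PWF)
#'
#' Monotone (non-decreasing) estimate of P(DE | length): probes are pooled
#' into equal-count length bins, the per-bin DE fractions are fitted by
#' weighted pool-adjacent-violators, and fitted values are clipped to
#' (0, 1).  Binning before the isotonic fit plays the smoothing role of a
#' monotone spline: a raw isotonic fit to 0/1 data is degenerate at the
#' length extremes (its edge values are single-observation suffix means).
#'
#' @param de_status named logical/0-1 vector: DE call per probe.
#' @param lengths numeric vector of probe lengths (bp), aligned with
#'   `de_status` (or named; matched by name when both are named).
#' @param bins number of equal-count length bins (default
#'   `max(2, min(n / 200, 30))`; a single distinct length collapses to one
#'   bin, giving the constant fit = global DE fraction).
#' @return An object of class `pwf`: data.frame with `probe_id`, `length`,
#'   `pwf`.
#' @export
fit_pwf <- function(de_status, lengths, bins = NULL) {
  if (!is.null(names(de_status)) && !is.null(names(lengths))) {
    lengths <- lengths[names(de_status)]
  }
  if (length(de_status) != length(lengths) || any(is.na(lengths))) {
    stop_fmt("fit_pwf: de_status and lengths must align")
  }
  de <- as.numeric(de_status)
  n <- length(de)
  if (all(de == 1) || all(de == 0)) {
    stop_fmt("fit_pwf: need at least one DE and one non-DE probe")
  }
  if (is.null(bins)) bins <- max(2L, min(floor(n / 200), 30L))
  br <- unique(stats::quantile(lengths, probs = seq(0, 1,
                                                    length.out = bins + 1)))
  grp <- if (length(br) < 2) rep(1L, n) else
    as.integer(cut(lengths, br, include.lowest = TRUE))
  agg <- tapply(de, grp, mean)
  wts <- tapply(de, grp, length)
  mid <- tapply(lengths, grp, mean)
  o <- order(mid)
  fit <- .pava(as.numeric(agg)[o], as.numeric(wts)[o])
  fit <- pmin(pmax(fit, 1e-6), 1 - 1e-6)
  # piecewise-linear in length between bin centres (monotone is preserved;
  # a step function would be off by the within-bin slope at the bin edges)
  w <- if (length(fit) == 1) rep(fit, n) else
    stats::approx(as.numeric(mid)[o], fit, xout = lengths, rule = 2,
                  ties = "ordered")$y
  ids <- if (!is.null(names(de_status))) names(de_status) else
    paste0("p", seq_along(de_status))
  structure(data.frame(probe_id = ids, length = lengths, pwf = w,
                       stringsAsFactors = FALSE),
            method = "binned isotonic", bins = length(unique(grp)),
            class = c("pwf", "data.frame"))
}

# Wallenius noncentral hypergeometric pmf by numerical integration of
#   P(X = x) = C(m1, x) C(m2, n - x) *
#              \int_0^1 (1 - t^(omega/D))^x (1 - t^(1/D))^(n-x) dt,
# D = omega (m1 - x) + (m2 - (n - x)).  The central case omega = 1 is the
# ordinary hypergeometric and is delegated to dhyper.

# log pmf of one support point, by quadrature of the transformed density
.ldwnchg_one <- function(x, m1, m2, n, odds) {
  d <- odds * (m1 - x) + (m2 - (n - x))
  if (d <= 0) {
    # all balls drawn: the single attainable x has probability 1
    return(if (x == n && m1 + m2 == n) 0 else -Inf)
  }
  a1 <- odds / d
  a2 <- 1 / d
  # substitute t = exp(-s): the [0, 1] integrand is a sharp spike near 0
  # for large n, but on [0, Inf) it is smooth and unimodal
  logf <- function(s) {
    term1 <- if (x > 0) x * log1p(-exp(-a1 * s)) else 0
    term2 <- if (n - x > 0) (n - x) * log1p(-exp(-a2 * s)) else 0
    term1 + term2 - s
  }
  # peak-shift so the integral never underflows for large counts
  peak <- stats::optimize(logf, c(1e-10, 50 * (n + d)), maximum = TRUE)
  M <- peak$objective
  I <- stats::integrate(function(s) exp(logf(s) - M), 0, Inf,
                        rel.tol = 1e-12, abs.tol = 0,
                        subdivisions = 2000L)$value
  lchoose(m1, x) + lchoose(m2, n - x) + M + log(I)
}

#' Wallenius noncentral hypergeometric mass function
#'
#' Distribution of the number of "white" balls obtained when `n` balls are
#' drawn sequentially without replacement from an urn of `m1` white and
#' `m2` other balls, each white ball having `odds` times the sampling
#' weight of an other ball.  `odds = 1` reduces exactly to the central
#' hypergeometric distribution.
#'
#' @param x vector of counts.
#' @param m1,m2 white / other ball counts.
#' @param n number of draws (`n <= m1 + m2`).
#' @param odds weight ratio (> 0, finite).
#' @return Probabilities `P(X = x)`.
#' @export
dwnchg <- function(x, m1, m2, n, odds) {
  if (!is.finite(odds) || odds <= 0) stop_fmt("dwnchg: odds must be positive and finite")
  if (n > m1 + m2) stop_fmt("dwnchg: more draws than balls")
  if (abs(odds - 1) < 1e-12) return(stats::dhyper(x, m1, m2, n))
  support <- max(0, n - m2):min(n, m1)
  lp <- vapply(support, .ldwnchg_one, numeric(1), m1 = m1, m2 = m2, n = n,
               odds = odds)
  pmf <- exp(lp - max(lp))
  pmf <- pmf / sum(pmf)
  out <- numeric(length(x))
  hit <- x %in% support
  out[hit] <- pmf[match(x[hit], support)]
  out
}

#' Wallenius noncentral hypergeometric tail probabilities
#'
#' @inheritParams dwnchg
#' @param q quantile.
#' @param lower.tail if `TRUE` (default) returns `P(X <= q)`, else
#'   `P(X >= q)` (note: inclusive, unlike [stats::phyper()]).
#' @return Tail probability.
#' @export
pwnchg <- function(q, m1, m2, n, odds, lower.tail = TRUE) {
  support <- max(0, n - m2):min(n, m1)
  pmf <- dwnchg(support, m1, m2, n, odds)
  if (lower.tail) sum(pmf[support <= q]) else sum(pmf[support >= q])
}

#' Length-bias-aware category enrichment (Wallenius test)
#'
#' For each category, the draw odds are the mean PWF weight of category
#' members over the mean weight of the complement; over- and under-
#' representation p-values are Wallenius noncentral hypergeometric tails
#' at the observed DE count, and a two-sided p (`min(1, 2 min(tails))`)
#' is adjusted across categories by Benjamini-Hochberg (default).
#'
#' @param de_status named logical/0-1 DE indicator over the gene universe.
#' @param annotation an `annotation_map` (only probes in the universe are
#'   considered).
#' @param pwf a [fit_pwf()] result over the same universe.
#' @param p_adjust `"BH"` (default) or `"bonferroni"` across categories.
#' @return An object of class `enrichment_result`: data.frame with
#'   `category`, `n_cat`, `n_de_in_cat`, `odds`, `p_over`, `p_under`,
#'   `p_two_sided`, `p_adj`, sorted by `p_adj`.
#' @export
wallenius_enrichment <- function(de_status, annotation, pwf,
                                 p_adjust = c("BH", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(annotation, "annotation_map"), inherits(pwf, "pwf"))
  universe <- pwf$probe_id
  de <- as.logical(de_status[universe])
  if (any(is.na(de))) stop_fmt("wallenius_enrichment: de_status missing for some universe probes")
  weights <- stats::setNames(pwf$pwf, pwf$probe_id)
  n_de_total <- sum(de)
  names(de) <- universe
  cats <- annotation$categories
  cats <- cats[cats$probe_id %in% universe, , drop = FALSE]
  rows <- lapply(split(cats$probe_id, cats$category), function(members) {
    n_cat <- length(members)
    n_in <- sum(de[members])
    outside <- setdiff(universe, members)
    if (!length(outside)) {
      warn_fmt("category spans the whole universe; reported degenerate")
      return(data.frame(n_cat = n_cat, n_de_in_cat = n_in, odds = NA_real_,
                        p_over = 1, p_under = 1))
    }
    odds <- mean(weights[members]) / mean(weights[outside])
    if (!is.finite(odds) || odds <= 0) {
      warn_fmt("non-finite odds for a category; skipped")
      return(NULL)
    }
    m1 <- n_cat
    m2 <- length(universe) - n_cat
    data.frame(
      n_cat = n_cat, n_de_in_cat = n_in, odds = odds,
      p_over = pwnchg(n_in, m1, m2, n_de_total, odds, lower.tail = FALSE),
      p_under = pwnchg(n_in, m1, m2, n_de_total, odds, lower.tail = TRUE))
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  out <- cbind(category = names(rows)[keep], out)
  out$p_two_sided <- pmin(1, 2 * pmin(out$p_over, out$p_under))
  out$p_adj <- stats::p.adjust(out$p_two_sided,
                               method = if (p_adjust == "BH") "BH" else "bonferroni")
  out <- out[order(out$p_adj, out$p_two_sided), ]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
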