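#' @keywords internal
"_PACKAGE"

# Canonical factor level orderings used throughout the pipeline.  The first
# level of each pair is the "positive" orientation of log2 ratios and model
# estimates (e.g. positive species estimates mean higher in A. gerardii).
.FACTORS <- list(
  species     = c("Ag", "Sn"),
  water       = c("watered", "drought"),
  temperature = c("ambient", "heated"),
  date        = c("day4", "day18")
)

.MAIN_TERMS <- c("species", "water", "temperature", "date")
.INT_TERMS  <- c("species:water", "species:temperature", "water:temperature")
.ALL_TERMS  <- c(.MAIN_TERMS, .INT_TERMS)

.DYES <- c("ch1", "ch2")

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used by the module-recovery tests; exported because planted-structure
#' benchmarks are part of this package's contract.
#'
#' @param a,b integer or character labels of equal length.
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_fmt("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) return(1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Greedy column selection for a design matrix: keep columns in the given
# order, dropping any column (numerically) in the span of those already kept.
# Returns the indices kept.  Order encodes marginality priority (intercept,
# then main effects, then interactions) so aliasing is attributed to the
# highest-order term involved.
.keep_columns <- function(X, tol = 1e-8) {
  kept <- integer(0)
  Q <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    r <- if (is.null(Q)) v else v - Q %*% crossprod(Q, v)
    if (sqrt(sum(r^2)) > tol * max(1, sqrt(sum(v^2)))) {
      kept <- c(kept, j)
      q <- r / sqrt(sum(r^2))
      Q <- cbind(Q, q)
    }
  }
  kept
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
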