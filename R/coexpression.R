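# Weighted coexpression module detection: soft-thresholded unsigned
# adjacency, topological overlap matrix (TOM), average-linkage clustering
# with a static cut, and module eigengene / trait association.  Defaults
# mirror the published analysis (minimum module size 5, day-18 samples,
# trait = species), with a fixed soft power of 6 and a deterministic
# static tree cut.

#' Topological overlap matrix
#'
#' Adjacency is `|pearson cor|^power` (unsigned network).  The TOM entry
#' for genes i, j is `(sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 -
#' a_ij)` with connectivity `k_i = sum_u a_iu`; the diagonal is 1.
#' Genes with missing values or zero variance are dropped first.
#'
#' @param expr genes x samples numeric matrix.
#' @param power soft-thresholding exponent (default 6).
#' @return TOM similarity matrix (symmetric, entries in \[0, 1\],
#'   diagonal 1) over the retained genes.
#' @export
compute_tom <- function(expr, power = 6) {
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  has_na <- rowSums(is.na(expr)) > 0
  if (any(has_na)) {
    message(sprintf("compute_tom: %d gene(s) with missing values dropped",
                    sum(has_na)))
    expr <- expr[!has_na, , drop = FALSE]
  }
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warn_fmt("compute_tom: %d constant gene(s) dropped", sum(v == 0))
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 5) stop_fmt("compute_tom: need >= 5 usable genes")
  if (ncol(expr) < 4) stop_fmt("compute_tom: need >= 4 samples")
  a <- abs(stats::cor(t(expr)))^power
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a                       # sum_u a_iu a_uj  (diag a = 0)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  stopifnot(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  pmin(pmax(tom, 0), 1)
}

#' Detect coexpression modules by static tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height; clusters smaller than `min_module_size` are set
#' to the unassigned label 0; remaining modules are renumbered 1, 2, ...
#' by decreasing size.
#'
#' @param tom TOM similarity matrix from [compute_tom()].
#' @param min_module_size smallest cluster reported as a module (default 5).
#' @param cut_height static cut height on 1 - TOM (default 0.95).
#' @return An object of class `module_result`: list with `labels` (named
#'   integer vector, 0 = unassigned), `params` and the `hclust` tree.
#' @export
detect_modules <- function(tom, min_module_size = 5, cut_height = 0.95) {
  if (!isSymmetric(unname(tom))) stop_fmt("detect_modules: TOM must be symmetric")
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  names(labels) <- names(raw)
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  }
  structure(list(labels = labels, tree = tree,
                 params = list(min_module_size = min_module_size,
                               cut_height = cut_height)),
            class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  n_mod <- max(x$labels)
  cat(sprintf("module_result: %d module(s) over %d genes (%d unassigned)\n",
              n_mod, length(x$labels), sum(x$labels == 0)))
  if (n_mod > 0) {
    sizes <- table(x$labels[x$labels > 0])
    cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  }
  if (!is.null(x$trait_association)) {
    print(x$trait_association)
  }
  invisible(x)
}

# First principal component of the gene-standardized module submatrix,
# scaled to unit variance and sign-oriented to correlate positively with
# the average member gene.
.module_eigengene <- function(expr, members) {
  sub <- expr[members, , drop = FALSE]
  z <- t(scale(t(sub)))
  z <- z[stats::complete.cases(z), , drop = FALSE]   # constant genes
  if (nrow(z) == 0) return(rep(0, ncol(sub)))
  sv <- svd(t(z), nu = 1, nv = 0)
  e <- sv$u[, 1]
  if (stats::sd(e) > 0) e <- e / stats::sd(e)
  m <- mean(stats::cor(e, t(z)), na.rm = TRUE)
  if (is.finite(m) && m < 0) e <- -e
  e
}

#' Module eigengenes and trait association
#'
#' Computes each module's eigengene (first principal component of the
#' standardized module submatrix, unit variance, sign-oriented to the
#' member genes) and its Pearson correlation with a binary trait, with a
#' Student-t p-value on n - 2 degrees of freedom.
#'
#' @param modules a `module_result` from [detect_modules()].
#' @param expr genes x samples matrix the modules were detected on.
#' @param trait binary (or numeric) trait per sample.
#' @return The `module_result` completed with `eigengenes` (samples x
#'   modules) and `trait_association` (data.frame `module`, `size`, `r`,
#'   `p_value`).
#' @export
module_trait_association <- function(modules, expr, trait) {
  stopifnot(inherits(modules, "module_result"))
  trait <- as.numeric(as.factor(trait))
  n <- ncol(expr)
  if (length(trait) != n) stop_fmt("trait length must equal sample count")
  if (min(table(trait)) < 3) stop_fmt("need >= 3 samples per trait level")
  labs <- modules$labels
  mods <- sort(unique(labs[labs > 0]))
  eig <- matrix(NA_real_, nrow = n, ncol = length(mods),
                dimnames = list(colnames(expr), paste0("ME", mods)))
  assoc <- do.call(rbind, lapply(seq_along(mods), function(i) {
    members <- names(labs)[labs == mods[i]]
    e <- .module_eigengene(expr, members)
    eig[, i] <<- e
    if (stats::sd(e) == 0 || stats::sd(trait) == 0) {
      return(data.frame(module = mods[i], size = length(members), r = 0,
                        p_value = 1))
    }
    r <- stats::cor(e, trait)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    data.frame(module = mods[i], size = length(members), r = r,
               p_value = min(p, 1))
  }))
  modules$eigengenes <- eig
  modules$trait_association <- assoc
  modules
}
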