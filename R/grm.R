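#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_i * (1 - p_i)))` with `Z` the dosage matrix
#' centered by twice the allele frequency. Under Hardy-Weinberg
#' equilibrium the diagonal averages 1 + f (f the inbreeding coefficient)
#' and unrelated pairs average 0. `G` is invariant to marker polarity
#' flips when the frequencies are re-estimated from the flipped dosages.
#'
#' @param Z centered clone x marker dosage matrix (see
#'   [impute_and_center()]).
#' @param p allele frequencies matching the columns of `Z`.
#' @return An object of class `relationship_matrix`: list with `values`
#'   (symmetric matrix, clone ids as dimnames), `clone_ids`, `kind`
#'   (`"vanraden_G"`), `blend` (0 until [grm_inverse()] blends).
#' @examples
#' geno <- genotype_table(matrix(c(0, 2, 2, 0), 2, 2,
#'   dimnames = list(c("a", "b"), c("m1", "m2"))))
#' zc <- impute_and_center(geno)
#' vanraden_grm(zc$Z, zc$p)$values  # ((2, -2), (-2, 2))
#' @export
vanraden_grm <- function(Z, p) {
  stopifnot(is.matrix(Z), length(p) == ncol(Z))
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) hcn_stop("all markers monomorphic: VanRaden denominator is zero")
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  relationship_matrix(G, kind = "vanraden_G")
}

relationship_matrix <- function(values, kind, blend = 0) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-10)
    hcn_stop("relationship matrix is not symmetric")
  if (is.null(rownames(values)))
    hcn_stop("relationship matrix needs clone ids as dimnames")
  structure(list(values = values, clone_ids = rownames(values),
                 kind = kind, blend = blend),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("relationship_matrix [", x$kind, "]: ", length(x$clone_ids), " clones",
      if (x$blend > 0) paste0("; blended ", x$blend), "\n", sep = "")
  invisible(x)
}

as_rel_values <- function(K) {
  if (inherits(K, "relationship_matrix")) K$values else K
}

#' Blended inverse of a relationship matrix
#'
#' Inverts `G* = (1 - blend) G + blend I`. Blending with the identity
#' (default 2%) is the standard bending that makes a singular `G`
#' (duplicated clones, more clones than markers) invertible while
#' preserving the ranking of breeding values.
#'
#' @param G a `relationship_matrix` or plain symmetric matrix.
#' @param blend identity weight in \[0, 1).
#' @return list: `inverse`, `blend`, `values` (the blended matrix).
#' @export
grm_inverse <- function(G, blend = 0.02) {
  V <- as_rel_values(G)
  Vb <- (1 - blend) * V + blend * diag(nrow(V))
  dimnames(Vb) <- dimnames(V)
  inv <- tryCatch(solve(Vb),
                  error = function(e)
                    hcn_stop("relationship matrix is singular even after ",
                             "blending (blend = ", blend, "): ",
                             conditionMessage(e)))
  list(inverse = inv, blend = blend, values = Vb)
}

#' Kinship diagnostics on a relationship matrix
#'
#' Summaries of the diagonal (self-kinship, 1 + inbreeding) and
#' off-diagonal (pairwise relatedness) distributions, plus the pairs above
#' a relatedness threshold (duplicates and full sibs sit near the diagonal
#' level, around 0.5 and above for full sibs).
#'
#' @param G a `relationship_matrix` or plain symmetric matrix.
#' @param threshold flag pairs with relatedness above this value.
#' @return list: `diagonal` and `offdiagonal` (min/mean/max), and
#'   `extreme_pairs` (data.frame `clone_a`, `clone_b`, `value`).
#' @export
kinship_diagnostics <- function(G, threshold = 0.9) {
  V <- as_rel_values(G)
  d <- diag(V)
  off <- V[upper.tri(V)]
  pairs_idx <- which(upper.tri(V) & V > threshold, arr.ind = TRUE)
  extreme <- data.frame(clone_a = rownames(V)[pairs_idx[, 1]],
                        clone_b = colnames(V)[pairs_idx[, 2]],
                        value = V[pairs_idx], stringsAsFactors = FALSE)
  extreme <- extreme[order(-extreme$value), , drop = FALSE]
  rownames(extreme) <- NULL
  list(diagonal = c(min = min(d), mean = mean(d), max = max(d)),
       offdiagonal = c(min = min(off), mean = mean(off), max = max(off)),
       extreme_pairs = extreme)
}

#' Principal component analysis of a relationship matrix
#'
#' Eigendecomposition of `G`; variance-explained fractions are eigenvalues
#' over the trace, components in decreasing order. Warns if `G` has
#' negative eigenvalues beyond numerical tolerance (non-PSD input).
#'
#' @param G a `relationship_matrix` or plain symmetric matrix.
#' @param n_components number of score columns to return.
#' @return list: `eigenvalues`, `scores` (clones x components, scaled by
#'   sqrt(eigenvalue)), `var_explained`.
#' @export
grm_pca <- function(G, n_components = 10) {
  V <- as_rel_values(G)
  e <- eigen(V, symmetric = TRUE)
  tr <- sum(diag(V))
  if (any(e$values < -1e-8 * max(tr, 1)))
    warning("relationship matrix is not positive semi-definite (eigenvalue ",
            signif(min(e$values), 3), ")")
  k <- min(n_components, ncol(V))
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  dimnames(scores) <- list(rownames(V), paste0("PC", seq_len(k)))
  list(eigenvalues = e$values, scores = scores,
       var_explained = e$values / tr)
}

#' Write/read a square relationship matrix as CSV
#'
#' Square layout with a leading `clone_id` column and clone ids as header.
#'
#' @param G a `relationship_matrix`.
#' @param path file path.
#' @return `write_grm` the path; `read_grm` a `relationship_matrix`.
#' @export
write_grm <- function(G, path) {
  stopifnot(inherits(G, "relationship_matrix"))
  df <- data.frame(clone_id = G$clone_ids, G$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @param kind matrix kind label for the object read back.
#' @export
read_grm <- function(path, kind = "vanraden_G") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  rownames(V) <- df[[1]]
  V <- (V + t(V)) / 2   # absorb round-trip rounding
  relationship_matrix(V, kind = kind)
}
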