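#' Fuse miRNA functional similarity with family membership
#'
#' `SIM(i, j) = SM(i, j) * (1 + SMfam(i, j))`: the functional-similarity score
#' of a same-family pair is doubled, reflecting the higher functional
#' coherence of miRNAs sharing a miRBase family. The diagonal is never
#' boosted. Entries may exceed 1 after the boost; downstream column
#' normalization absorbs the scale, so no clamping is applied.
#'
#' @param sm Symmetric miRNA functional-similarity matrix, entries in `[0, 1]`,
#'   with labels.
#' @param family Named character vector mapping miRNA id to family id (miRNAs
#'   absent from it are unassigned), or an already-built 0/1 co-membership
#'   matrix from [family_matrix()].
#' @return The fused similarity matrix, symmetric, entries in `[0, 2]`.
#' @export
fuse_mirna_similarity <- function(sm, family) {
  stopifnot(is.matrix(sm), nrow(sm) == ncol(sm), !is.null(rownames(sm)))
  if (min(sm) < 0 || max(sm) > 1)
    stop("miRNA similarity entries must lie in [0, 1]", call. = FALSE)
  fm <- if (is.matrix(family)) family else family_matrix(family, rownames(sm))
  if (!identical(dimnames(fm), dimnames(sm)))
    stop("family matrix labels do not match the similarity matrix",
         call. = FALSE)
  sm * (1 + fm)
}

#' Column-normalize a non-negative matrix
#'
#' Divides every column with positive sum by that sum, making it a probability
#' column of the walk's transition matrix; all-zero columns (isolated
#' entities) are left as zero columns.
#'
#' @param m Non-negative numeric matrix.
#' @return Matrix of the same shape whose nonzero columns sum to 1.
#' @export
column_normalize <- function(m) {
  stopifnot(is.matrix(m))
  if (min(m) < 0)
    stop("cannot column-normalize a matrix with negative entries",
         call. = FALSE)
  cs <- colSums(m)
  nz <- cs > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2L, cs[nz], "/")
  m
}

#' Global network similarity by Laplacian smoothing
#'
#' For a similarity network with column-normalized transition matrix
#' \eqn{\bar S}, the global-similarity profile of entity j is the Laplacian
#' graph score \eqn{\tilde d = (1 - a) (I - a \bar S)^{-1} e_j}: the smoothed
#' indicator of j, balancing propagation over the network (weight `balance`)
#' against fidelity to the query. All profiles are obtained at once as
#' \eqn{G = (1 - a)(I - a\bar S)^{-1}}; column j of the result is entity j's
#' profile. The linear system is solved directly (LU solve against the
#' identity); for `balance < 1` and column-stochastic \eqn{\bar S} the system
#' matrix is provably non-singular.
#'
#' @param s Raw (un-normalized) similarity matrix with labels; column
#'   normalization is applied internally.
#' @param balance Smoothing balance in the open interval (0, 1). As
#'   `balance` approaches 0 the result approaches the identity.
#' @return Labeled square matrix of global-similarity scores, entries
#'   non-negative; columns over fully-stochastic networks sum to 1.
#' @export
global_similarity <- function(s, balance) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  if (!is.numeric(balance) || length(balance) != 1L || is.na(balance) ||
      balance <= 0 || balance >= 1)
    stop("'balance' must be a single number strictly inside (0, 1)",
         call. = FALSE)
  sbar <- column_normalize(s)
  n <- nrow(sbar)
  g <- (1 - balance) * solve(diag(n) - balance * sbar, diag(n))
  if (!all(is.finite(g)))
    stop("global-similarity solve produced non-finite values", call. = FALSE)
  # round-off can leave entries a hair below zero; anything worse is a bug
  neg <- min(g)
  if (neg < -1e-10)
    stop("global-similarity solve produced negative entries (min ",
         format(neg), ")", call. = FALSE)
  g[g < 0] <- 0
  dimnames(g) <- dimnames(s)
  g
}
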