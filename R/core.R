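#' Optimize a disease walk seed
#'
#' Augments the disease's own association vector with the similarity-weighted
#' association vectors of the other diseases:
#' \eqn{\tilde D_i = D_i + \lambda \sum_{j \ne i} sim\tilde D(d_i, d_j) D_0^j}.
#' The self term is excluded (including it would re-add \eqn{D_i} scaled by
#' the disease's self-similarity). The result is L1-normalized to a
#' probability vector when nonzero; an all-zero seed (orphan disease in a
#' similarity vacuum) is returned as-is with attribute `zero = TRUE`.
#'
#' @param a Binary association matrix, rows = miRNAs, columns = diseases.
#' @param sim_d_global Disease global-similarity matrix from
#'   [global_similarity()].
#' @param lam Seed weight, non-negative.
#' @param disease_index Column index of the query disease.
#' @return Numeric vector over miRNAs summing to 1 (or all-zero, flagged).
#' @export
optimize_disease_seed <- function(a, sim_d_global, lam, disease_index) {
  stopifnot(disease_index >= 1L, disease_index <= ncol(a),
            ncol(a) == nrow(sim_d_global), lam >= 0)
  # column i is the query disease's smoothed global profile over diseases
  g <- sim_d_global[, disease_index]
  g[disease_index] <- 0
  seed <- a[, disease_index] + lam * as.vector(a %*% g)
  .normalize_seed(seed)
}

#' Optimize an miRNA walk seed
#'
#' Mirror of [optimize_disease_seed()] on the miRNA side:
#' \eqn{\tilde M_j = M_j + \eta \sum_{i \ne j} sim\tilde M(m_j, m_i) M_0^i}.
#'
#' @param a Binary association matrix, rows = miRNAs, columns = diseases.
#' @param sim_m_global miRNA global-similarity matrix.
#' @param eta Seed weight, non-negative.
#' @param mirna_index Row index of the query miRNA.
#' @return Numeric vector over diseases summing to 1 (or all-zero, flagged).
#' @export
optimize_mirna_seed <- function(a, sim_m_global, eta, mirna_index) {
  stopifnot(mirna_index >= 1L, mirna_index <= nrow(a),
            nrow(a) == nrow(sim_m_global), eta >= 0)
  # column j is the query miRNA's smoothed global profile over miRNAs
  g <- sim_m_global[, mirna_index]
  g[mirna_index] <- 0
  seed <- a[mirna_index, ] + eta * as.vector(crossprod(a, g))
  .normalize_seed(seed)
}

.normalize_seed <- function(seed) {
  s <- sum(seed)
  if (s > 0) {
    seed <- seed / s
    attr(seed, "zero") <- FALSE
  } else {
    attr(seed, "zero") <- TRUE
  }
  seed
}

#' Random walk with restart
#'
#' Iterates \eqn{x_{t+1} = (1 - r) \bar S x_t + r \cdot seed} from
#' \eqn{x_0 = seed} until the L1 change between successive iterates drops
#' below `tol` (default `1e-6`). The fixed point ranks network nodes by
#' proximity to the seed distribution. An all-zero seed short-circuits to an
#' all-zero result.
#'
#' @param s_bar Column-normalized transition matrix.
#' @param seed Probability vector over nodes (sums to 1), or all-zero.
#' @param restart Restart probability in (0, 1]; each step returns to the seed
#'   with this probability.
#' @param tol L1 convergence threshold.
#' @param max_iter Iteration cap; exceeding it without convergence is an
#'   error reporting the last residual.
#' @return The stationary distribution vector; non-negative, and summing to 1
#'   when `s_bar` has no zero columns.
#' @export
random_walk_restart <- function(s_bar, seed, restart, tol = 1e-6,
                                max_iter = 1000L) {
  stopifnot(is.matrix(s_bar), nrow(s_bar) == ncol(s_bar),
            length(seed) == nrow(s_bar))
  if (!is.numeric(restart) || restart <= 0 || restart > 1)
    stop("'restart' must lie in (0, 1]", call. = FALSE)
  seed <- as.vector(seed)
  if (all(seed == 0)) return(seed)
  prop <- 1 - restart
  x <- seed
  for (iter in seq_len(max_iter)) {
    x_new <- prop * as.vector(s_bar %*% x) + restart * seed
    resid <- sum(abs(x_new - x))
    x <- x_new
    if (resid < tol) return(x)
  }
  stop("random walk did not converge in ", max_iter,
       " iterations (last L1 residual ", format(resid), ")", call. = FALSE)
}

#' Score candidates by Pearson correlation with global-similarity profiles
#'
#' Entry k is the Pearson correlation between the walk's stationary
#' distribution and column k of the global-similarity matrix (entity k's
#' global profile). A zero-variance stationary vector or profile column gives
#' a score of 0 rather than NaN.
#'
#' @param stationary Stationary distribution from [random_walk_restart()].
#' @param global_sim Global-similarity matrix whose columns are entity
#'   profiles.
#' @return Numeric vector of scores in `[-1, 1]`, one per column.
#' @export
pearson_profile_scores <- function(stationary, global_sim) {
  stopifnot(is.matrix(global_sim))
  if (length(stationary) != nrow(global_sim))
    stop("stationary vector length (", length(stationary),
         ") does not match global-similarity dimension (", nrow(global_sim),
         ")", call. = FALSE)
  xc <- stationary - mean(stationary)
  sx <- sqrt(sum(xc^2))
  mc <- sweep(global_sim, 2L, colMeans(global_sim))
  sm <- sqrt(colSums(mc^2))
  num <- as.vector(crossprod(mc, xc))
  den <- sx * sm
  out <- numeric(ncol(global_sim))
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  pmin(1, pmax(-1, out))
}

#' Precompute association-independent network quantities
#'
#' The global-similarity matrices and the column-normalized transition
#' matrices depend only on the similarity networks, never on the association
#' matrix, so cross-validation reuses them across folds.
#'
#' @param sim_mirna Fused miRNA similarity matrix (see
#'   [fuse_mirna_similarity()]).
#' @param sim_disease Disease similarity matrix.
#' @param params A [gstrw_params()] object (uses `alpha`, `beta`).
#' @return List with `sim_m`, `sim_d` (global similarities) and `sbar_m`,
#'   `sbar_d` (transition matrices).
#' @export
precompute_globals <- function(sim_mirna, sim_disease,
                               params = gstrw_params()) {
  list(sim_m = global_similarity(sim_mirna, params$beta),
       sim_d = global_similarity(sim_disease, params$alpha),
       sbar_m = column_normalize(sim_mirna),
       sbar_d = column_normalize(sim_disease))
}

#' Two-tier random-walk association prediction
#'
#' The full predictor. Disease tier: for every disease, an optimized seed
#' walks with restart over the miRNA network and the stationary distribution
#' is correlated with every miRNA's global-similarity profile, giving the
#' disease x miRNA score matrix `F_m`. miRNA tier: the mirror walk over the
#' disease network gives the miRNA x disease matrix `F_d`. The final score is
#' the tier mixture `F = w * t(F_m) + (1 - w) * F_d` (miRNA x disease); a
#' high `F(i, j)` flags miRNA i as a likely associate of disease j. Known
#' pairs are not masked from `F`; ranking layers decide what to exclude.
#'
#' @param a Binary association matrix, rows = miRNAs, columns = diseases,
#'   dimnames aligned with the similarity matrices.
#' @param sim_mirna Fused miRNA similarity matrix.
#' @param sim_disease Disease similarity matrix.
#' @param params A [gstrw_params()] object.
#' @param globals Optional precomputed [precompute_globals()] result (must
#'   match `sim_mirna`, `sim_disease` and the `alpha`/`beta` in `params`).
#' @return List of class `"gstrw_scores"` with elements `F` (miRNA x
#'   disease), `F_m` (disease x miRNA), `F_d` (miRNA x disease) and `params`.
#' @export
#' @examples
#' fx <- synthetic_generate(synthetic_spec(n_mirna = 20, n_disease = 10,
#'                                         rng_seed = 7))
#' sim <- fuse_mirna_similarity(fx$sm, fx$family)
#' fit <- gstrw_predict(fx$a, sim, fx$sd)
#' dim(fit$F)
gstrw_predict <- function(a, sim_mirna, sim_disease,
                          params = gstrw_params(), globals = NULL) {
  reconcile_labels(sim_mirna, sim_disease, a)
  if (is.null(globals)) globals <- precompute_globals(sim_mirna, sim_disease,
                                                      params)
  n_m <- nrow(a); n_d <- ncol(a)

  f_m <- matrix(0, n_d, n_m, dimnames = list(colnames(a), rownames(a)))
  for (i in seq_len(n_d)) {
    seed <- optimize_disease_seed(a, globals$sim_d, params$lam, i)
    st <- random_walk_restart(globals$sbar_m, seed, params$gamma,
                              params$tol, params$max_iter)
    f_m[i, ] <- pearson_profile_scores(st, globals$sim_m)
  }

  f_d <- matrix(0, n_m, n_d, dimnames = list(rownames(a), colnames(a)))
  for (j in seq_len(n_m)) {
    seed <- optimize_mirna_seed(a, globals$sim_m, params$eta, j)
    st <- random_walk_restart(globals$sbar_d, seed, params$theta,
                              params$tol, params$max_iter)
    f_d[j, ] <- pearson_profile_scores(st, globals$sim_d)
  }

  f <- params$w * t(f_m) + (1 - params$w) * f_d
  structure(list(F = f, F_m = f_m, F_d = f_d, params = params),
            class = "gstrw_scores")
}

#' @export
print.gstrw_scores <- function(x, ...) {
  cat(sprintf("gstrw score matrices: %d miRNAs x %d diseases (w = %g)\n",
              nrow(x$F), ncol(x$F), x$params$w))
  invisible(x)
}
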