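#' Predictor parameters
#'
#' Bundles every scalar knob of the two-tier random-walk predictor. The
#' defaults are the setting used for the method's headline comparison runs.
#'
#' @param gamma Restart probability of the disease-seed walk on the miRNA
#'   network, strictly inside (0, 1).
#' @param theta Restart probability of the miRNA-seed walk on the disease
#'   network, strictly inside (0, 1).
#' @param alpha Laplacian-smoothing balance of the disease network, in (0, 1).
#'   Larger values propagate the query indicator further over the network.
#' @param beta Laplacian-smoothing balance of the miRNA network, in (0, 1).
#' @param lam Seed-optimization weight for diseases (contribution of similar
#'   diseases' association vectors to the walk seed), non-negative.
#' @param eta Seed-optimization weight for miRNAs, non-negative.
#' @param w Tier-mixing weight in `[0, 1]`: `w = 1` uses only the miRNA-network
#'   tier, `w = 0` only the disease-network tier.
#' @param tol Convergence threshold for the walks, on the L1 change between
#'   successive iterates.
#' @param max_iter Iteration cap for the walks.
#'
#' @return A list of class `"gstrw_params"`.
#' @export
#' @examples
#' gstrw_params()
#' gstrw_params(w = 1) # miRNA-network tier only
gstrw_params <- function(gamma = 0.2, theta = 0.2,
                         alpha = 0.8, beta = 0.8,
                         lam = 0.2, eta = 0.2,
                         w = 0.6,
                         tol = 1e-6, max_iter = 1000L) {
  chk_unit_open <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
      stop("'", nm, "' must be a single number strictly inside (0, 1), got ",
           format(x), call. = FALSE)
  }
  chk_unit_open(gamma, "gamma")
  chk_unit_open(theta, "theta")
  chk_unit_open(alpha, "alpha")
  chk_unit_open(beta, "beta")
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("'lam' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(eta) || length(eta) != 1L || is.na(eta) || eta < 0)
    stop("'eta' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("'w' must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol <= 0)
    stop("'tol' must be a single positive number", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    stop("'max_iter' must be a positive integer", call. = FALSE)
  structure(
    list(gamma = gamma, theta = theta, alpha = alpha, beta = beta,
         lam = lam, eta = eta, w = w, tol = tol, max_iter = max_iter),
    class = "gstrw_params"
  )
}

#' @export
print.gstrw_params <- function(x, ...) {
  cat("gstrw parameters:\n")
  cat(sprintf("  restart        gamma = %g, theta = %g\n", x$gamma, x$theta))
  cat(sprintf("  smoothing      alpha = %g, beta  = %g\n", x$alpha, x$beta))
  cat(sprintf("  seed weights   lam   = %g, eta   = %g\n", x$lam, x$eta))
  cat(sprintf("  tier weight    w     = %g\n", x$w))
  cat(sprintf("  convergence    tol = %g, max_iter = %d\n", x$tol, x$max_iter))
  invisible(x)
}
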