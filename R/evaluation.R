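#' ROC curve and AUC from positive and negative score pools
#'
#' Sweeps the decision threshold over all distinct scores, recording (false
#' positive rate, true positive rate) at each, and integrates the curve by the
#' trapezoid rule. Equal scores move both coordinates in a single step, so the
#' trapezoidal area equals the Mann-Whitney U convention
#' \eqn{P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)}: a constant predictor scores
#' exactly 0.5.
#'
#' @param pos_scores Scores of the positive (known/held-out) pairs.
#' @param neg_scores Scores of the candidate (unknown) pairs.
#' @return List with `roc` (data frame `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L)
    stop("need at least one positive and one negative score", call. = FALSE)
  scores <- c(pos_scores, neg_scores)
  is_pos <- rep(c(1L, 0L), c(np, nn))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- is_pos[o]
  cum_tp <- cumsum(l)
  cum_fp <- cumsum(1L - l)
  # close each tie group: keep the last index of every run of equal scores
  last <- c(s[-length(s)] != s[-1L], TRUE)
  tpr <- c(0, cum_tp[last] / np)
  fpr <- c(0, cum_fp[last] / nn)
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1L]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall points from positive and negative score pools
#'
#' Precision and recall of the classifier "score >= threshold" at every
#' distinct threshold, in descending-score order.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `recall`, `precision`.
#' @export
precision_recall <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L)
    stop("need at least one positive and one negative score", call. = FALSE)
  scores <- c(pos_scores, neg_scores)
  is_pos <- rep(c(1L, 0L), c(np, nn))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- is_pos[o]
  last <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(l)[last]
  n_pred <- which(last)
  data.frame(threshold = s[last],
             recall = tp / np,
             precision = tp / n_pred)
}

.new_eval_result <- function(protocol, pos_scores, neg_scores,
                             per_query_ranks) {
  ra <- roc_auc(pos_scores, neg_scores)
  structure(
    list(protocol = protocol,
         roc_points = ra$roc,
         auc = ra$auc,
         pr_points = precision_recall(pos_scores, neg_scores),
         per_query_ranks = per_query_ranks,
         pos_scores = pos_scores,
         neg_scores = neg_scores),
    class = "gstrw_eval"
  )
}

#' @export
print.gstrw_eval <- function(x, ...) {
  cat(sprintf("gstrw evaluation [%s]: AUC = %.4f (%d positives, %d negatives)\n",
              x$protocol, x$auc, length(x$pos_scores), length(x$neg_scores)))
  invisible(x)
}

# rank of `score` among `pool` (which excludes it), Mann-Whitney tie credit;
# returned as a relative rank in (0, 1]: 1/(n+1) = best possible
.relative_rank <- function(score, pool) {
  r <- 1 + sum(pool > score) + 0.5 * sum(pool == score)
  r / (length(pool) + 1)
}

#' Leave-one-out cross-validation of the predictor
#'
#' Each known pair is removed in turn, the predictor is rerun on the reduced
#' association matrix, and the held-out pair's score is recorded. Candidate
#' negatives are all pairs unknown in the full matrix. With the default
#' `pooling = "global"` the negatives are scored once by a reference run on
#' the full matrix and all held-out positives are ranked against this single
#' pool; with `pooling = "per_disease"` each fold contributes its own
#' disease-column negatives, scored within the fold. Global-similarity and
#' transition matrices are computed once and shared across folds (they do not
#' depend on the association matrix).
#'
#' @param a Binary association matrix with at least 2 known pairs.
#' @param sim_mirna Fused miRNA similarity matrix.
#' @param sim_disease Disease similarity matrix.
#' @param params A [gstrw_params()] object.
#' @param pooling Candidate-pool convention, `"global"` (default) or
#'   `"per_disease"`.
#' @return A `"gstrw_eval"` object; `per_query_ranks` maps each held-out pair
#'   (named `"mirna|disease"`) to its relative rank in its candidate pool
#'   (small = good).
#' @export
gstrw_loocv <- function(a, sim_mirna, sim_disease, params = gstrw_params(),
                        pooling = c("global", "per_disease")) {
  pooling <- match.arg(pooling)
  pairs <- which(a == 1, arr.ind = TRUE)
  if (nrow(pairs) < 2L)
    stop("leave-one-out cross-validation needs at least 2 known pairs",
         call. = FALSE)
  globals <- precompute_globals(sim_mirna, sim_disease, params)

  neg_mask <- a == 0
  pos_scores <- numeric(nrow(pairs))
  ranks <- numeric(nrow(pairs))
  names(pos_scores) <- names(ranks) <-
    paste(rownames(a)[pairs[, 1L]], colnames(a)[pairs[, 2L]], sep = "|")

  if (pooling == "global") {
    full_fit <- gstrw_predict(a, sim_mirna, sim_disease, params, globals)
    neg_scores <- full_fit$F[neg_mask]
  } else {
    neg_scores <- NULL
  }

  for (k in seq_len(nrow(pairs))) {
    m <- pairs[k, 1L]; d <- pairs[k, 2L]
    a_fold <- a
    a_fold[m, d] <- 0L
    fit <- gstrw_predict(a_fold, sim_mirna, sim_disease, params, globals)
    pos_scores[k] <- fit$F[m, d]
    if (pooling == "global") {
      ranks[k] <- .relative_rank(pos_scores[k], neg_scores)
    } else {
      fold_neg <- fit$F[neg_mask[, d], d]
      neg_scores <- c(neg_scores, fold_neg)
      ranks[k] <- .relative_rank(pos_scores[k], fold_neg)
    }
  }
  .new_eval_result("loocv_pairs", pos_scores, neg_scores, ranks)
}

# shared machinery of the orphan-disease / new-miRNA protocols; `margin` = 2
# zeroes disease columns, `margin` = 1 zeroes miRNA rows
.holdout_entity_eval <- function(a, sim_mirna, sim_disease, params, margin,
                                 protocol) {
  n_entities <- dim(a)[margin]
  if (n_entities < 2L)
    stop("entity hold-out needs at least 2 ",
         if (margin == 2L) "diseases" else "miRNAs",
         " (no similar entities to borrow associations from)", call. = FALSE)
  globals <- precompute_globals(sim_mirna, sim_disease, params)
  known_per_entity <- if (margin == 2L) colSums(a) else rowSums(a)
  queries <- which(known_per_entity >= 1)
  if (length(queries) == 0L)
    stop("no entity has any known association", call. = FALSE)

  pos_scores <- numeric(0)
  neg_scores <- numeric(0)
  ranks <- numeric(0)
  for (q in queries) {
    a_fold <- a
    if (margin == 2L) a_fold[, q] <- 0L else a_fold[q, ] <- 0L
    fit <- gstrw_predict(a_fold, sim_mirna, sim_disease, params, globals)
    if (margin == 2L) {
      removed <- which(a[, q] == 1)
      sc_pos <- fit$F[removed, q]
      sc_neg <- fit$F[a[, q] == 0, q]
      nm <- paste(rownames(a)[removed], colnames(a)[q], sep = "|")
    } else {
      removed <- which(a[q, ] == 1)
      sc_pos <- fit$F[q, removed]
      sc_neg <- fit$F[q, a[q, ] == 0]
      nm <- paste(rownames(a)[q], colnames(a)[removed], sep = "|")
    }
    r <- vapply(sc_pos, .relative_rank, numeric(1L), pool = sc_neg)
    names(r) <- nm
    pos_scores <- c(pos_scores, stats::setNames(sc_pos, nm))
    neg_scores <- c(neg_scores, sc_neg)
    ranks <- c(ranks, r)
  }
  .new_eval_result(protocol, pos_scores, neg_scores, ranks)
}

#' Orphan-disease evaluation
#'
#' Simulates each disease in turn as an orphan: its entire association column
#' is zeroed, the predictor is rerun, and the scores of the removed pairs are
#' recorded as positives against the disease's never-known pairs scored in
#' the same run. Only the seed-optimization step (borrowing associations from
#' similar diseases) can recover signal here.
#'
#' @inheritParams gstrw_loocv
#' @return A `"gstrw_eval"` object with protocol `"orphan_disease"`.
#' @export
orphan_disease_eval <- function(a, sim_mirna, sim_disease,
                                params = gstrw_params()) {
  .holdout_entity_eval(a, sim_mirna, sim_disease, params, 2L,
                       "orphan_disease")
}

#' New-miRNA evaluation
#'
#' Mirror of [orphan_disease_eval()]: each miRNA's association row is zeroed
#' in turn and its removed pairs are scored against the miRNA's never-known
#' pairs.
#'
#' @inheritParams gstrw_loocv
#' @return A `"gstrw_eval"` object with protocol `"new_mirna"`.
#' @export
new_mirna_eval <- function(a, sim_mirna, sim_disease,
                           params = gstrw_params()) {
  .holdout_entity_eval(a, sim_mirna, sim_disease, params, 1L, "new_mirna")
}

# parameter groups swept together, matching how the method's sensitivity
# analysis ties the two restart, balance and seed weights
.sweep_groups <- list(
  gamma_theta = c("gamma", "theta"),
  alpha_beta = c("alpha", "beta"),
  lam_eta = c("lam", "eta"),
  gamma = "gamma", theta = "theta", alpha = "alpha", beta = "beta",
  lam = "lam", eta = "eta", w = "w"
)

#' One-at-a-time parameter sweep
#'
#' Varies one parameter (or tied parameter group) at a time while holding the
#' others at `base_params`, running the chosen evaluation protocol at each
#' value. Grid names may be individual parameters (`"w"`, `"gamma"`, ...) or
#' the tied groups `"gamma_theta"`, `"alpha_beta"`, `"lam_eta"`.
#'
#' @inheritParams gstrw_loocv
#' @param grid Named list mapping a parameter (group) name to the numeric
#'   values to try.
#' @param protocol One of `"loocv_pairs"`, `"orphan_disease"`, `"new_mirna"`.
#' @param base_params Parameters held fixed while each group is varied.
#' @return Data frame with columns `param`, `value`, `auc`.
#' @export
parameter_sweep <- function(a, sim_mirna, sim_disease, grid,
                            protocol = c("loocv_pairs", "orphan_disease",
                                         "new_mirna"),
                            base_params = gstrw_params()) {
  protocol <- match.arg(protocol)
  stopifnot(is.list(grid), !is.null(names(grid)))
  unknown <- setdiff(names(grid), names(.sweep_groups))
  if (length(unknown))
    stop("unknown sweep parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  run <- switch(protocol,
    loocv_pairs = function(p) gstrw_loocv(a, sim_mirna, sim_disease, p)$auc,
    orphan_disease = function(p)
      orphan_disease_eval(a, sim_mirna, sim_disease, p)$auc,
    new_mirna = function(p) new_mirna_eval(a, sim_mirna, sim_disease, p)$auc)
  rows <- list()
  for (g in names(grid)) {
    for (v in grid[[g]]) {
      p <- unclass(base_params)
      p[.sweep_groups[[g]]] <- v
      rows[[length(rows) + 1L]] <-
        data.frame(param = g, value = v, auc = run(do.call(gstrw_params, p)))
    }
  }
  do.call(rbind, rows)
}
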