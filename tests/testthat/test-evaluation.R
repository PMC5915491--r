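test_that("ROC/AUC handles separation and ties like the U statistic", {
  expect_equal(roc_auc(c(3, 2), c(1, 0))$auc, 1.0)
  expect_equal(roc_auc(1, 1)$auc, 0.5)
  expect_equal(roc_auc(rep(2, 5), rep(2, 7))$auc, 0.5)  # constant predictor
  expect_equal(roc_auc(c(1, 2), c(3, 4))$auc, 0.0)
})

test_that("trapezoidal AUC equals exhaustive pair counting", {
  set.seed(51)
  for (i in 1:15) {
    # coarse score grids force plenty of ties
    pos <- sample(seq(0, 1, 0.1), 50, replace = TRUE)
    neg <- sample(seq(0, 1, 0.1), 50, replace = TRUE)
    ra <- roc_auc(pos, neg)
    expect_equal(ra$auc, auc_u_oracle(pos, neg), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  pos <- sample(seq(0, 1, 0.1), 40, replace = TRUE)
  neg <- sample(seq(0, 1, 0.1), 60, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(40, 60)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(pos, neg)$auc, ref, tolerance = 1e-12)
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(52)
  roc <- roc_auc(rnorm(30, 1), rnorm(40))$roc
  expect_identical(unlist(roc[1, ], use.names = FALSE), c(0, 0))
  expect_identical(unlist(roc[nrow(roc), ], use.names = FALSE), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("precision-recall matches confusion-matrix enumeration", {
  set.seed(53)
  for (i in 1:10) {
    pos <- round(rnorm(40, 1), 2)
    neg <- round(rnorm(60), 2)
    expect_equal(precision_recall(pos, neg), pr_enum_oracle(pos, neg),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # perfect separation: precision 1 at every threshold
  pr <- precision_recall(c(5, 6, 7), c(1, 2))
  expect_true(all(pr$precision[pr$threshold >= 5] == 1))
  # inverted scores: at full recall precision equals prevalence
  pr2 <- precision_recall(c(1, 2), c(5, 6, 7, 8))
  expect_equal(pr2$precision[pr2$recall == 1][1], 2 / 6)
})

test_that("LOOCV pools scores consistently with the pairwise oracle", {
  fx <- small_fixture()
  sim <- small_fused(fx)
  res <- gstrw_loocv(fx$a, sim, fx$sd)
  expect_s3_class(res, "gstrw_eval")
  expect_identical(res$protocol, "loocv_pairs")
  expect_identical(length(res$pos_scores), sum(fx$a == 1))
  expect_identical(length(res$neg_scores), sum(fx$a == 0))
  expect_equal(res$auc, auc_u_oracle(res$pos_scores, res$neg_scores),
               tolerance = 1e-12)
  # AUC recomputed from the reported ROC points by trapezoid agrees too
  roc <- res$roc_points
  expect_equal(sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2),
               res$auc, tolerance = 1e-12)
})

test_that("LOOCV per-disease pooling ranks within disease columns", {
  fx <- small_fixture()
  sim <- small_fused(fx)
  res <- gstrw_loocv(fx$a, sim, fx$sd, pooling = "per_disease")
  expect_identical(length(res$pos_scores), sum(fx$a == 1))
  expect_identical(length(res$neg_scores), as.integer(
    sum(vapply(seq_len(ncol(fx$a)), function(d)
      sum(fx$a[, d] == 0) * sum(fx$a[, d] == 1), numeric(1)))))
  expect_true(all(res$per_query_ranks > 0 & res$per_query_ranks <= 1))
})

test_that("LOOCV refuses degenerate inputs", {
  fx <- tiny_dataset()
  a1 <- fx$a; a1[] <- 0L; a1[1, 1] <- 1L
  expect_error(gstrw_loocv(a1, fx$sm, fx$sd), "at least 2 known pairs")
})

test_that("entity hold-out protocols score from the zeroed matrix only", {
  fx <- small_fixture()
  sim <- small_fused(fx)
  params <- gstrw_params()
  globals <- precompute_globals(sim, fx$sd, params)
  res <- orphan_disease_eval(fx$a, sim, fx$sd, params)
  # recompute one query independently: zero the column, rerun predict
  d <- which(colSums(fx$a) >= 1)[2]
  a0 <- fx$a; a0[, d] <- 0L
  fit <- gstrw_predict(a0, sim, fx$sd, params, globals)
  removed <- which(fx$a[, d] == 1)
  nm <- paste(rownames(fx$a)[removed], colnames(fx$a)[d], sep = "|")
  expect_equal(unname(res$pos_scores[nm]), unname(fit$F[removed, d]),
               tolerance = 1e-12)

  resm <- new_mirna_eval(fx$a, sim, fx$sd, params)
  m <- which(rowSums(fx$a) >= 1)[3]
  am <- fx$a; am[m, ] <- 0L
  fitm <- gstrw_predict(am, sim, fx$sd, params, globals)
  removedm <- which(fx$a[m, ] == 1)
  nmm <- paste(rownames(fx$a)[m], colnames(fx$a)[removedm], sep = "|")
  expect_equal(unname(resm$pos_scores[nmm]), unname(fitm$F[m, removedm]),
               tolerance = 1e-12)
})

test_that("single-entity datasets cannot run entity hold-out", {
  fx <- tiny_dataset()
  expect_error(orphan_disease_eval(fx$a[, 1, drop = FALSE], fx$sm,
                                   fx$sd[1, 1, drop = FALSE]),
               "at least 2 diseases")
  expect_error(new_mirna_eval(fx$a[1, , drop = FALSE],
                              fx$sm[1, 1, drop = FALSE], fx$sd),
               "at least 2 miRNAs")
})

test_that("a disease with no informative similarity yields tie-rank scores", {
  # disease d2 is similar to nothing and has the only association column that
  # is zeroed: its seed is zero, all its scores are 0, ranked by tie credit
  sd <- diag(3); dimnames(sd) <- list(paste0("d", 1:3), paste0("d", 1:3))
  sm <- rand_sim(4L, paste0("m", 1:4))
  a <- matrix(0L, 4, 3, dimnames = list(rownames(sm), rownames(sd)))
  a[1, 2] <- 1L; a[2, 1] <- 1L; a[3, 3] <- 1L
  res <- orphan_disease_eval(a, sm, sd, gstrw_params(w = 1))
  sc <- res$pos_scores[grep("d2", names(res$pos_scores))]
  expect_identical(unname(sc), 0)
})

test_that("parameter sweeps reproduce ablation endpoints and are deterministic", {
  fx <- small_fixture()
  sim <- small_fused(fx)
  tab <- parameter_sweep(fx$a, sim, fx$sd, list(w = c(0, 1)))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$auc[tab$value == 0],
               gstrw_loocv(fx$a, sim, fx$sd, gstrw_params(w = 0))$auc)
  expect_equal(tab$auc[tab$value == 1],
               gstrw_loocv(fx$a, sim, fx$sd, gstrw_params(w = 1))$auc)
  tab2 <- parameter_sweep(fx$a, sim, fx$sd, list(w = c(0, 1)))
  expect_identical(tab, tab2)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_error(parameter_sweep(fx$a, sim, fx$sd, list(bogus = 1)),
               "unknown sweep parameter")
})

test_that("tied restart parameters sweep as one group", {
  fx <- small_fixture()
  sim <- small_fused(fx)
  tab <- parameter_sweep(fx$a, sim, fx$sd, list(gamma_theta = c(0.2, 0.5)))
  expect_identical(tab$param, rep("gamma_theta", 2L))
  direct <- gstrw_loocv(fx$a, sim, fx$sd,
                        gstrw_params(gamma = 0.5, theta = 0.5))$auc
  expect_equal(tab$auc[tab$value == 0.5], direct)
})
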