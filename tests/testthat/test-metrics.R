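test_that("universality is the median over predictors and is order-invariant", {
  cfg <- tiny_config()
  w <- make_latents(cfg)
  study <- build_study(w)
  plan <- fold_plan(cfg$n_stim_eval, 5, seed = 1)
  target <- study$targets[[1]]$Y[, 1]
  preds <- lapply(2:3, function(i) {
    pool_activation_set(make_network(w, i, "eval"))
  })
  u <- universality_score(target, preds, plan)
  expect_equal(u$universality, median(u$per_predictor_r))
  u_rev <- universality_score(target, rev(preds), plan)
  expect_equal(u$universality, u_rev$universality, tolerance = 1e-12)
  expect_equal(sort(u$per_predictor_r), sort(u_rev$per_predictor_r),
               tolerance = 1e-12)
  expect_error(universality_score(target, list(), plan), "empty predictor")
})

test_that("median aggregation is robust to single-predictor outliers", {
  r <- c(0.9, 0.2, 0.8)
  expect_equal(median(r), 0.8)
  # replacing one score moves the median at most to the adjacent order stat
  r2 <- c(0.9, -5, 0.8)
  expect_equal(median(r2), 0.8)
  r3 <- c(0.9, 99, 0.8)
  expect_equal(median(r3), 0.9)
})

test_that("brain similarity is the subject mean and aligns rows strictly", {
  cfg <- tiny_config()
  w <- make_latents(cfg)
  study <- build_study(w)
  plan <- fold_plan(cfg$n_stim_eval, 5, seed = 1)
  target <- study$targets[[1]]$Y[, 1]
  b <- brain_similarity_score(target, study$brains, plan)
  expect_equal(b$brain_similarity, mean(b$per_subject_r))
  expect_error(brain_similarity_score(target[-1], study$brains, plan),
               "shape error")
  # uncorrelated noise subjects: near-zero brain similarity
  set.seed(9)
  noise_subjects <- lapply(1:2, function(s) {
    matrix(rnorm(cfg$n_stim_eval * 20), cfg$n_stim_eval, 20)
  })
  bn <- brain_similarity_score(target, noise_subjects, plan)
  expect_lt(abs(bn$brain_similarity), 0.25)
})

test_that("between-subject reliability is high for shared signal, near zero for disjoint", {
  cfg <- tiny_config(brain_noise_sd = 0.01)
  w <- make_latents(cfg)
  study <- build_study(w)
  plan <- fold_plan(cfg$n_stim_eval, 5, seed = 2)
  # target carrying the brain latent: reliability near 1
  target <- drop(w$Z_brain[split_indices(cfg)$eval, 1])
  rel <- between_subject_reliability(target, study$brains, plan)
  expect_gt(rel, 0.9)
  expect_equal(between_subject_reliability(target, study$brains[1], plan),
               NA_real_)
  # subject-order invariance
  expect_equal(rel,
               between_subject_reliability(target, rev(study$brains), plan),
               tolerance = 1e-12)
  # disjoint latents with realistic voxel noise: each subject's prediction
  # of an unrelated target is dominated by its own noise fit, so the
  # predictions decorrelate. (With nearly noiseless subjects sharing one
  # low-rank space, predictions of any target collapse onto the same
  # projection and reliability is high regardless of predictability —
  # reliability bounds consistency, not predictability.)
  rels <- vapply(1:5, function(s) {
    wn <- make_null_world(tiny_config(seed = 70 + s, brain_noise_sd = 1,
                                      n_voxels = 30))
    sn <- build_study(wn)
    between_subject_reliability(sn$targets[[1]]$Y[, 1], sn$brains, plan)
  }, numeric(1))
  expect_lt(mean(rels), 0.2)
})

test_that("reliability adjustment follows the attenuation-correction convention", {
  expect_equal(reliability_adjust(0.45, 0.81), 0.5)
  expect_equal(reliability_adjust(0.33, 1), 0.33)
  expect_true(is.na(reliability_adjust(0.4, 0.05)))
  expect_true(is.na(reliability_adjust(0.4, NA)))
  expect_equal(reliability_adjust(0.4, 0.64, divisor = "raw"), 0.625)
})

test_that("quantile bins are equally sized with the partial bin dropped", {
  tb <- data.frame(universality = seq(0, 1, length.out = 200),
                   brain_similarity = seq(0, 2, length.out = 200))
  qb <- quantile_bin_means(tb, 100)
  expect_equal(nrow(qb), 2L)
  expect_equal(qb$mean_universality,
               c(mean(tb$universality[1:100]), mean(tb$universality[101:200])))
  tb2 <- data.frame(universality = runif(250), brain_similarity = runif(250))
  expect_equal(nrow(quantile_bin_means(tb2, 100)), 2L)
  expect_error(quantile_bin_means(tb, 0), "bin_size")
})

test_that("score table aggregates are recomputable from stored per-predictor lists", {
  cfg <- tiny_config()
  study <- build_study(make_latents(cfg))
  plan <- fold_plan(cfg$n_stim_eval, 5, seed = 3)
  tbl <- score_dimensions(study, plan)
  R <- attr(tbl, "per_predictor_r")
  B <- attr(tbl, "per_subject_r")
  expect_equal(ncol(R), cfg$n_networks - 1L)
  expect_equal(ncol(B), cfg$n_subjects)
  expect_equal(tbl$universality, apply(R, 1, median))
  expect_equal(tbl$brain_similarity, rowMeans(B))
  # unique dimension key
  key <- paste(tbl$network_id, tbl$layer_id, tbl$pc_rank)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("planted shared dimensions dominate universality and brain similarity", {
  fx <- aligned_fixture()
  hi <- fx$shared_fraction >= 0.9
  lo <- fx$shared_fraction <= 0.1
  expect_gt(sum(hi), 0)
  # every nearly-pure shared PC is recovered with very high universality
  expect_true(all(fx$tbl$universality[hi] > 0.9))
  # the idiosyncratic/noise bulk stays low in its central mass (the extreme
  # upper tail carries small shared leakage plus sampling noise)
  expect_lt(median(fx$tbl$universality[lo]), 0.05)
  expect_lt(quantile(fx$tbl$universality[lo], 0.9), 0.15)
  # brain similarity separates the planted class in every paired comparison
  frac <- mean(outer(fx$tbl$brain_similarity[hi],
                     fx$tbl$brain_similarity[lo], ">"))
  expect_gte(frac, 0.95)
  # ground-truth alignment: shared-variance fraction and universality agree
  expect_gt(as.numeric(spearman_rho(fx$shared_fraction[hi | lo],
                                    fx$tbl$universality[hi | lo])), 0)
  expect_gt(cor(fx$shared_fraction, fx$tbl$universality), 0.8)
})

test_that("quantile trend rises on the aligned world", {
  fx <- aligned_fixture()
  qb <- quantile_bin_means(fx$tbl, 100)
  expect_equal(nrow(qb), nrow(fx$tbl) %/% 100)
  # trend: strong overall increase; any local inversions stay within the
  # noise scale of a 100-dimension bin mean
  expect_gt(as.numeric(spearman_rho(qb$bin, qb$mean_brain_similarity)), 0.5)
  inv <- diff(qb$mean_brain_similarity)
  expect_true(all(inv > -0.02))
  expect_equal(which.max(qb$mean_brain_similarity), nrow(qb))
})
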