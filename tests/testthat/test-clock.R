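grad_config <- function(attn_scale) {
  clock_config(d_embed = 4, n_heads = 2, n_blocks = 1,
               head_hidden = c(8, 16, 8), attn_scale = attn_scale, seed = 1)
}

test_that("analytic gradients match central differences", {
  expect_lt(nn_grad_check(grad_config("sqrt")), 1e-4)
  expect_lt(nn_grad_check(grad_config("linear")), 1e-4)
  # deeper trunk as well
  cfg <- clock_config(d_embed = 4, n_heads = 2, n_blocks = 2,
                      head_hidden = c(8, 8), seed = 1)
  expect_lt(nn_grad_check(cfg), 1e-4)
})

test_that("configuration is validated", {
  expect_error(clock_config(dropout = 0.5), "dropout")
  expect_error(clock_config(attn_scale = "cubic"), "arg")
  expect_error(clock_config(d_embed = 0), "positive")
  expect_error(init_params(clock_config(d_embed = 6, n_heads = 4), 3, c(2, 2)),
               "multiple")
})

test_that("fitting is deterministic and carves validation from train only", {
  fx <- tiny_clock()
  refit <- multiclock(fx$stacked, fx$split,
                      clock_config(d_embed = 4, n_heads = 2, n_blocks = 1,
                                   head_hidden = c(16, 32, 16),
                                   max_epochs = 100, patience = 20, seed = 5))
  expect_identical(refit$params, fx$fit$params)
  expect_identical(refit$trainlog, fx$fit$trainlog)
  expect_true(all(fx$fit$val_ids %in% fx$split$train_ids))
  expect_length(intersect(fx$fit$val_ids, fx$split$test_ids), 0)
  expect_lte(nrow(fx$fit$trainlog), 100)
  expect_lte(fx$fit$best_epoch, nrow(fx$fit$trainlog))
})

test_that("the clock learns a planted age signal at small scale", {
  pp <- preprocess_cohort(cohort_spec(n_per_modality = 150, n_genes = 60,
                                      n_age_genes = 20, seed = 61))
  fit <- multiclock(pp$stacked, pp$split, small_config())
  expect_lt(fit$metrics$combined$mae, 0.5 * const_mae(pp))
  # both modalities individually beat the constant predictor
  for (mod in c("methylation", "expression"))
    expect_lt(fit$metrics[[mod]]$mae, 0.75 * const_mae(pp))
})

test_that("on a no-signal cohort the clock does not pretend to learn", {
  pp <- preprocess_cohort(cohort_spec(n_per_modality = 100, n_genes = 40,
                                      n_age_genes = 0, effect_size = 0,
                                      seed = 67))
  fit <- multiclock(pp$stacked, pp$split, small_config())
  cm <- const_mae(pp)
  expect_gt(fit$metrics$combined$mae, 0.9 * cm)
  expect_lt(fit$metrics$combined$mae, 1.5 * cm)
})

test_that("regression metrics match hand-computed values", {
  m <- evaluate_regression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_equal(m$r2, 0)            # SSE 2 over SST 2
  expect_equal(m$mdae, 1)
  expect_equal(m$n, 3L)
  expect_true(is.na(evaluate_regression(c(1, 2), c(5, 5))$r2))
  expect_error(evaluate_regression(1:3, 1:2), "equal length")
  expect_error(evaluate_regression(1, 1), "at least 2")
})

test_that("prediction validates tokens, features and scaling", {
  fx <- tiny_clock()
  test <- fx$stacked[fx$split$test_ids, ]
  attr(test, "prescaled") <- TRUE
  pred <- predict(fx$fit, test)
  expect_equal(unname(pred), fx$fit$predictions$predicted)
  # raw-unit path: scaling applied internally gives the same answer
  raw_me <- fx$meth_gene[intersect(fx$split$test_ids,
                                   fx$meth_gene$metadata$sample_id), ]
  pred_raw <- predict(fx$fit, raw_me)
  expect_equal(pred_raw, pred[names(pred_raw)])
  # unknown tissue token
  bad <- test
  bad$metadata$tissue[1] <- "T99"
  expect_error(predict(fx$fit, bad), "T99")
  # missing model feature
  short <- test
  short$values <- short$values[, -1, drop = FALSE]
  expect_error(predict(fx$fit, short), "lacks model feature")
})

test_that("model methods expose the classic interface", {
  fx <- tiny_clock()
  fit <- fx$fit
  expect_output(print(fit), "aging clock")
  expect_output(print(fit), "test MAE")
  expect_output(summary(fit), "MAE")
  expect_identical(coef(fit), fit$params)
  r <- residuals(fit)
  expect_equal(unname(r), fit$predictions$age - fit$predictions$predicted)
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, "learning"))
  grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("trajectory scoring validates its input and reports a trend", {
  fx <- tiny_clock()
  spec <- cohort_spec(n_per_modality = 60, n_genes = 8, n_age_genes = 4,
                      seed = 41)
  traj <- simulate_trajectory(spec, "maturation", n_timepoints = 4,
                              n_replicates = 3)
  rep <- predict_trajectory(fx$fit, traj)
  expect_equal(nrow(rep$per_timepoint), 4)
  expect_true(rep$rho >= -1 && rep$rho <= 1)
  expect_true(rep$trend %in% c("rejuvenation", "maturation", "none"))
  expect_output(print(rep), "Spearman")
  no_time <- traj
  no_time$metadata$time <- NULL
  expect_error(predict_trajectory(fx$fit, no_time), "time")
  two <- traj[traj$metadata$time <= 2, ]
  expect_error(predict_trajectory(fx$fit, two), "3 distinct")
})

test_that("fitting refuses unusable metadata", {
  fx <- tiny_clock()
  noage <- fx$stacked
  noage$metadata$age[3] <- NA
  expect_error(multiclock(noage, fx$split), "ages must be present")
})
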