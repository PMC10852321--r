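test_that("robust Mahalanobis scores are calibrated and affine invariant", {
  set.seed(5)
  x <- matrix(rnorm(2000 * 5), ncol = 5)
  colnames(x) <- paste0("f", 1:5)
  mod <- train_mahalanobis(x, seed = 6)
  # score at the fitted location is zero
  expect_equal(sqrt(mahalanobis(t(mod$center), mod$center, mod$cov)), 0)
  # squared scores of Gaussian data are chi-square(5): QQ slope 1 +- 0.1
  d2 <- mahalanobis(x, mod$center, mod$cov)
  slope <- coef(lm(sort(d2) ~ 0 + qchisq((seq_len(2000) - 0.5) / 2000, 5)))
  expect_lt(abs(slope - 1), 0.1)
  # invertible affine transform leaves scores unchanged
  Q <- qr.Q(qr(matrix(rnorm(25), 5))) %*% diag(c(2, 1, 0.5, 1.5, 1))
  b <- rnorm(5)
  xt <- x %*% Q + rep(1, 2000) %o% b
  colnames(xt) <- colnames(x)
  mod2 <- train_mahalanobis(xt, seed = 6)
  y <- matrix(rnorm(50), ncol = 5)
  s1 <- sqrt(mahalanobis(y, mod$center, mod$cov))
  s2 <- sqrt(mahalanobis(y %*% Q + rep(1, 10) %o% b, mod2$center, mod2$cov))
  expect_equal(s1, s2, tolerance = 1e-6)
  # degenerate inputs are refused with a pointer at the feature set
  xs <- cbind(x, x[, 5])
  expect_error(train_mahalanobis(xs, seed = 1), "feature")
  expect_error(train_mahalanobis(x[1:20, ], seed = 1), "10 rows")
})

test_that("isolation forest isolates outliers and respects its contracts", {
  set.seed(8)
  x <- matrix(rnorm(3000 * 4), ncol = 4)
  colnames(x) <- paste0("f", 1:4)
  mod <- train_isolation_forest(x, seed = 3)
  sc_train <- surflesion:::iso_score(mod$forest, x[1:500, ])
  expect_true(all(sc_train >= 0 & sc_train <= 1))
  out <- matrix(10, 1, 4)
  expect_gt(surflesion:::iso_score(mod$forest, out), median(sc_train))
  mod2 <- train_isolation_forest(x, seed = 3)
  expect_identical(surflesion:::iso_score(mod2$forest, x[1:100, ]),
                   surflesion:::iso_score(mod$forest, x[1:100, ]))
  expect_warning(train_isolation_forest(x[1:100, ], psi = 2048, seed = 1),
                 "lowered")
})

test_that("the random forest comparator learns with a 1:10 class ratio", {
  set.seed(12)
  x_ctrl <- matrix(rnorm(4000 * 3), ncol = 3)
  x_les <- matrix(rnorm(150 * 3, mean = 3), ncol = 3)
  colnames(x_ctrl) <- colnames(x_les) <- paste0("f", 1:3)
  mod <- train_rfc(x_ctrl, x_les, seed = 4)
  expect_equal(mod$n_control, 10 * mod$n_lesional)
  held_les <- matrix(rnorm(100 * 3, mean = 3), ncol = 3)
  held_ctrl <- matrix(rnorm(100 * 3), ncol = 3)
  colnames(held_les) <- colnames(held_ctrl) <- paste0("f", 1:3)
  p_les <- predict(mod$fit, data.frame(held_les),
                   num.threads = 1)$predictions[, "lesional"]
  p_ctrl <- predict(mod$fit, data.frame(held_ctrl),
                    num.threads = 1)$predictions[, "lesional"]
  expect_gt(mean(p_les), mean(p_ctrl))
  expect_error(train_rfc(x_ctrl, x_les[0, ]), "lesional")
})

test_that("training schedules implement the leave-one-out contracts", {
  co <- fixture_cohort()
  ids <- vapply(co$subjects, `[[`, "", "subject_id")
  ctrl <- ids[1:8]
  sched <- training_schedule(co, "MAH")
  # patients train on all controls; controls exclude themselves
  expect_equal(sched[["pos001"]]$controls, ctrl)
  expect_equal(sched[["ctrl003"]]$controls, setdiff(ctrl, "ctrl003"))
  sched_rfc <- training_schedule(co, "RFC")
  expect_equal(sched_rfc[["pos001"]]$lesional_subjects, "pos002")
  expect_equal(sched_rfc[["neg001"]]$lesional_subjects, c("pos001", "pos002"))
  expect_false("ctrl002" %in% sched[["ctrl002"]]$controls)
})

test_that("subject scoring post-smooths and preserves range contracts", {
  co <- fixture_cohort()
  m <- co$mesh
  fb <- augment_features(co)
  ids <- vapply(co$subjects, `[[`, "", "subject_id")
  std <- zscore_features(fb, ids[1:8])
  feats <- define_subsets(fb)$reduced_noflair
  maps <- score_cohort(co, std, feats, "IF", seed = 7, psi = 256)
  expect_named(maps, ids)
  for (mp in maps[c(1, 9, 11)]) {
    expect_true(mp$post_smoothed)
    expect_true(all(mp$values >= 0 & mp$values <= 1))
  }
  # MAH maps stay nonnegative through smoothing
  maps_mah <- score_cohort(co, std, feats, "MAH", seed = 7)
  expect_true(all(maps_mah[[1]]$values >= 0))
  # constant maps pass through smoothing unchanged
  mod <- train_isolation_forest(matrix(rnorm(600 * 2), ncol = 2,
                                       dimnames = list(NULL, c("a", "b"))),
                                psi = 128, seed = 1)
  const_bank <- matrix(0.5, m$nv, 2, dimnames = list(NULL, c("a", "b")))
  sc <- score_subject(mod, const_bank, m)
  expect_equal(sc$values, rep(sc$values[1], m$nv), tolerance = 1e-9)
  # feature-name mismatch is refused
  bad <- const_bank
  colnames(bad) <- c("a", "z")
  expect_error(score_subject(mod, bad, m), "feature")
})
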