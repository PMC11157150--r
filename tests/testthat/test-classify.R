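separable_features <- function(n_per_class = 40, seed = 1) {
  set.seed(seed)
  classes <- rep(c("grazing", "resting"), each = n_per_class)
  tibble::tibble(
    behaviour = classes,
    x_mean = ifelse(classes == "grazing", -300, 0) + rnorm(length(classes), 0, 10),
    odba = ifelse(classes == "grazing", 100, 10) + rnorm(length(classes), 0, 3),
    yz_sd = rnorm(length(classes))
  )
}

test_that("the train/test split is stratified, exhaustive and seed-stable", {
  ft <- separable_features(50, seed = 2)  # 100 rows
  sp <- split_train_test(ft, train_fraction = 0.75, seed = 1)
  expect_identical(nrow(sp$train), 75L)
  expect_identical(nrow(sp$test), 25L)
  # stratified: each class contributes close to its share
  expect_true(all(table(sp$train$behaviour) %in% 37:38))
  sp2 <- split_train_test(ft, train_fraction = 0.75, seed = 1)
  expect_identical(sp$train, sp2$train)
  partitions <- vapply(1:10, function(s) {
    paste(which(ft$x_mean %in% split_train_test(ft, seed = s)$test$x_mean),
          collapse = ",")
  }, character(1))
  expect_gt(length(unique(partitions)), 1L)
})

test_that("a singleton class stays whole in the training set with a warning", {
  ft <- separable_features(10, seed = 3)
  ft$behaviour[1] <- "running"
  expect_warning(sp <- split_train_test(ft, seed = 1), "kept whole")
  expect_true("running" %in% sp$train$behaviour)
  expect_false("running" %in% sp$test$behaviour)
})

test_that("training fits separable data perfectly and ignores unselected columns", {
  ft <- separable_features(seed = 4)
  model <- train_classifier(ft, c("x_mean", "odba"), seed = 1)
  expect_identical(predict_behaviour(model, ft), ft$behaviour)
  permuted <- ft
  set.seed(9)
  permuted$yz_sd <- sample(permuted$yz_sd)
  expect_identical(predict_behaviour(model, permuted),
                   predict_behaviour(model, ft))
  one_class <- ft[ft$behaviour == "grazing", ]
  expect_error(train_classifier(one_class, "x_mean"), "2 behaviour classes")
})

test_that("prediction is total and demands the training columns", {
  ft <- separable_features(seed = 5)
  model <- train_classifier(ft, c("x_mean", "odba"), seed = 1)
  expect_identical(predict_behaviour(model, ft[0, ]), character())
  expect_identical(length(predict_behaviour(model, ft)), nrow(ft))
  expect_error(predict_behaviour(model, ft[, c("behaviour", "x_mean")]),
               "absent")
})

test_that("cross-validation predicts every burst once and conserves counts", {
  ft <- separable_features(30, seed = 6)
  rep5 <- cross_validate(ft, c("x_mean", "odba"), folds = 5, seed = 1)
  expect_identical(sum(rep5$matrix), nrow(ft))
  expect_equal(unname(colSums(rep5$matrix)),
               unname(as.numeric(table(ft$behaviour)[rep5$labels])))
  # separable fixture: diagonal matrix, perfect precision/recall
  expect_identical(sum(diag(rep5$matrix)), nrow(ft))
  expect_equal(unname(rep5$precision), c(1, 1))
  expect_equal(unname(rep5$recall), c(1, 1))
})

test_that("confusion reports are internally consistent", {
  set.seed(7)
  labels <- c("a", "b", "c")
  obs <- sample(labels, 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.7, obs, sample(labels, 300, replace = TRUE))
  rep <- confusion_report(obs, pred)
  m <- rep$matrix
  expect_equal(rep$accuracy, sum(diag(m)) / sum(m))
  expect_equal(unname(rep$precision), unname(diag(m) / rowSums(m)))
  expect_equal(unname(rep$recall), unname(diag(m) / colSums(m)))
  expect_true(rep$ci["lower"] <= rep$accuracy && rep$accuracy <= rep$ci["upper"])
  expect_true(all(m >= 0))
})
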