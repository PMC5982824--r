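test_that("untrained models output softmax probabilities, deterministically under seed", {
  m1 <- build_cnn(cnn_spec(n_filters = 4L, dense = c(16L, 8L)), seed = 91)
  m2 <- build_cnn(cnn_spec(n_filters = 4L, dense = c(16L, 8L)), seed = 91)
  set.seed(1)
  X <- matrix(runif(5 * 132), 5, 132)
  p1 <- predict_sweeps(m1, X)
  p2 <- predict_sweeps(m2, X)
  probs <- as.matrix(p1[, class_levels()])
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-9)
  expect_true(all(probs >= 0))
  expect_identical(as.matrix(p1[, class_levels()]), as.matrix(p2[, class_levels()]))
})

test_that("analytic gradients match finite differences", {
  spec <- cnn_spec(n_filters = 2L, dense = c(6L, 4L),
                   dropout_conv = 0, dropout_dense = 0)
  m <- build_cnn(spec, seed = 92)
  set.seed(92)
  X <- matrix(runif(3 * 132), 3, 132)
  Y <- diag(5)[c(1, 3, 5), ]
  fwd <- sweepimage:::cnn_forward(m, X, training = TRUE)
  gr <- sweepimage:::cnn_backward(m, fwd, Y)
  loss_at <- function(mm) {
    f <- sweepimage:::cnn_forward(mm, X)
    -mean(rowSums(Y * log(pmax(f$probs, 1e-12))))
  }
  eps <- 1e-6
  for (nm in c("sq3_W1", "dil3_W2", "dil4_W1", "Wd1", "Wout", "bout")) {
    for (i in sample(length(m$params[[nm]]), 2)) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("prediction is invariant to batch composition", {
  m <- build_cnn(cnn_spec(n_filters = 4L, dense = c(16L, 8L)), seed = 93)
  set.seed(93)
  X <- matrix(runif(300 * 132), 300, 132)  # crosses the internal batch size
  whole <- sweepimage:::predict_probs(m, X)
  single <- t(vapply(seq_len(10), function(i) {
    sweepimage:::predict_probs(m, X[i, , drop = FALSE])[1, ]
  }, numeric(5)))
  expect_equal(whole[1:10, ], single, tolerance = 1e-10)
})

test_that("training separates a linearly separable two-pattern set", {
  set.seed(94)
  ts <- separable_set(60)
  m <- train_cnn(build_cnn(cnn_spec(n_filters = 4L, dense = c(16L, 8L)), seed = 94),
                 ts, train_config(max_epochs = 15, val_fraction = 0.2))
  expect_gte(max(m$history$val_accuracy), 0.99)
})

test_that("flat validation accuracy stops training after the patience window", {
  set.seed(95)
  ts <- separable_set(20)
  m <- train_cnn(build_cnn(cnn_spec(n_filters = 2L, dense = c(4L, 4L)), seed = 95),
                 ts, train_config(learning_rate = 0, max_epochs = 50, patience = 4))
  # epoch 1 sets the best; with frozen weights nothing improves afterwards
  expect_equal(nrow(m$history), 1L + 4L)
})

test_that("the row-order-free 12-row filter variant builds and learns", {
  spec <- cnn_spec(
    n_filters = 8L, dense = c(16L, 8L), dropout_conv = 0.1, dropout_dense = 0.1,
    branches = list(
      full3 = list(filter = c(12L, 3L), dilation = c(1L, 1L), pool = c(1L, 2L),
                   padding = "valid"),
      full2 = list(filter = c(12L, 2L), dilation = c(1L, 1L), pool = c(1L, 2L),
                   padding = "valid")))
  set.seed(96)
  ts <- separable_set(40)
  # the collapsed representation is small; a larger step size compensates
  m <- train_cnn(build_cnn(spec, seed = 96), ts,
                 train_config(learning_rate = 1e-2, max_epochs = 15,
                              val_fraction = 0.2, patience = 15))
  expect_gte(max(m$history$val_accuracy), 0.9)
})

test_that("incompatible architecture requests fail loudly", {
  expect_error(cnn_spec(branches = list(
    bad = list(filter = c(13L, 3L), dilation = c(1L, 1L), pool = c(2L, 2L)))),
    "exceeds")
  expect_error(cnn_spec(branches = list(
    bad = list(filter = c(2L, 2L), dilation = c(1L, 6L), pool = c(2L, 12L)))),
    "pool")
  expect_error(train_cnn(build_cnn(), tibble::tibble()), "empty")
  one_class <- separable_set(10)
  one_class <- one_class[one_class$label == "hard", ]
  expect_error(train_cnn(build_cnn(), one_class), "2 classes")
})

test_that("the Extra-Trees baseline yields probability vectors and is seed-stable", {
  set.seed(97)
  ts <- separable_set(30)
  et1 <- train_extratrees(ts, num_trees = 60, seed = 7)
  et2 <- train_extratrees(ts, num_trees = 60, seed = 7)
  p1 <- predict_sweeps(et1, ts)
  expect_equal(rowSums(as.matrix(p1[, class_levels()])), rep(1, nrow(ts)),
               tolerance = 1e-9)
  expect_identical(as.matrix(p1[, class_levels()]),
                   as.matrix(predict_sweeps(et2, ts)[, class_levels()]))
  expect_gte(mean(p1$pred == ts$label), 0.95)
})

test_that("rank AUC agrees with pair enumeration and an external reference", {
  set.seed(98)
  for (i in 1:5) {
    score <- round(runif(40), 2)  # ties likely
    pos <- runif(40) > 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(auc_rank(score, pos), oracle_auc(score, pos))
  }
  score <- c(rnorm(30), rnorm(30, 2))
  pos <- rep(c(FALSE, TRUE), each = 30)
  expect_equal(auc_rank(score, pos),
               as.numeric(suppressMessages(pROC::auc(pROC::roc(pos, score,
                                                               quiet = TRUE)))))
  expect_error(auc_rank(1:5, rep(TRUE, 5)), "both")
})

test_that("evaluation of a perfect and a uniform-random predictor behaves as expected", {
  register_mock_model()
  set.seed(99)
  n <- 100
  labs <- factor(sample(class_levels(), n, TRUE), levels = class_levels())
  perfect <- matrix(1e-9, n, 5)
  perfect[cbind(seq_len(n), as.integer(labs))] <- 1 - 4e-9
  ts <- tibble::as_tibble(matrix(runif(n * 132), n, 132,
                                 dimnames = list(NULL, feature_names())))
  ts$label <- labs
  ev <- evaluate_classifier(mock_model(perfect), ts)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
  expect_equal(unclass(ev$confusion_prop), diag(5), ignore_attr = TRUE)

  set.seed(100)
  m_rand <- matrix(rexp(n * 5 * 50), n * 50, 5)
  m_rand <- m_rand / rowSums(m_rand)
  labs_big <- factor(sample(class_levels(), n * 50, TRUE), levels = class_levels())
  ts_big <- tibble::as_tibble(matrix(0.5, n * 50, 132,
                                     dimnames = list(NULL, feature_names())))
  ts_big$label <- labs_big
  ev_r <- evaluate_classifier(mock_model(m_rand), ts_big)
  expect_lt(abs(ev_r$accuracy - 0.2), 0.03)
  expect_lt(abs(ev_r$auc - 0.5), 0.05)
})

test_that("confusion rows sum to one and tidy/glance expose the report", {
  register_mock_model()
  set.seed(101)
  n <- 60
  labs <- factor(sample(class_levels(), n, TRUE), levels = class_levels())
  pm <- matrix(rexp(n * 5), n, 5)
  pm <- pm / rowSums(pm)
  ts <- tibble::as_tibble(matrix(0.1, n, 132, dimnames = list(NULL, feature_names())))
  ts$label <- labs
  ev <- evaluate_classifier(mock_model(pm), ts)
  expect_equal(unname(rowSums(ev$confusion_prop)), rep(1, 5))
  td <- tidy(ev)
  expect_equal(nrow(td), 25L)
  expect_setequal(names(td), c("truth", "pred", "n", "fraction"))
  gl <- glance(ev)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("accuracy", "auc", "sweep_recall", "sweep_fpr") %in% names(gl)))
  expect_gte(gl$auc, 0)
  expect_lte(gl$auc, 1)

  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(gl, f)
  expect_equal(as.data.frame(readr::read_tsv(f, show_col_types = FALSE)),
               as.data.frame(gl), tolerance = 1e-12)
})

test_that("positional confusion records class fractions by sweep offset", {
  register_mock_model()
  labs <- factor(rep(c("hard", "linkedHard"), each = 4), levels = class_levels())
  wins <- c(6, 6, 6, 6, 2, 2, 9, 9)
  pm <- matrix(1e-9, 8, 5)
  pm[, 5] <- 1 - 4e-9  # everything called hard
  ts <- tibble::as_tibble(matrix(0.1, 8, 132, dimnames = list(NULL, feature_names())))
  ts$label <- labs
  ts$sweep_win <- wins
  ev <- evaluate_classifier(mock_model(pm), ts)
  expect_true(all(ev$positional$pred == "hard"))
  expect_setequal(unique(ev$positional$offset), c(0, -4, 3))
  expect_true(all(ev$positional$fraction == 1))
})
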