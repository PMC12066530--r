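test_that("stratified splitting matches class proportions at the group level", {
  recs <- tibble::tibble(
    recording_id = sprintf("r%03d", 1:100),
    severity = rep(c(0, 1, 2), times = c(50, 30, 20))
  )
  # two utterance rows per recording
  data <- dplyr::bind_rows(recs, recs)
  sp <- stratified_split(data, 0.25, seed = 3)
  test_recs <- dplyr::distinct(sp$test, recording_id, severity)
  tab <- table(factor(test_recs$severity, 0:2))
  expect_true(tab[["0"]] %in% 12:13)
  expect_true(tab[["1"]] %in% 7:8)
  expect_equal(tab[["2"]], 5L)
  # determinism and disjointness
  sp2 <- stratified_split(data, 0.25, seed = 3)
  expect_identical(sp$test$recording_id, sp2$test$recording_id)
  expect_length(intersect(sp$train$recording_id, sp$test$recording_id), 0L)
  few <- tibble::tibble(recording_id = 1:7, severity = c(0, 0, 0, 0, 1, 1, 1))
  expect_error(stratified_split(few, 0.25, 1), class = "prosodia_argument_error")
})

test_that("the correlation screen keeps one survivor per correlated group", {
  base <- withr::with_seed(13, {
    tibble::tibble(
      a = stats::rnorm(60), b = stats::rnorm(60), c = stats::rnorm(60)
    )
  })
  y <- as.integer(cut(base$a + stats::rnorm(60, 0, 0.2), 3, labels = FALSE)) - 1L
  # duplicated column: exactly one survivor of the pair
  X <- dplyr::mutate(base, a_dup = a)
  flt <- filter_correlated(X, y)
  expect_equal(sum(c("a", "a_dup") %in% flt$kept), 1L)
  # three mutually correlated columns: the one closest to y survives
  X2 <- tibble::tibble(
    A = base$a + stats::rnorm(60, 0, 0.01),
    B = base$a,
    C = base$a - stats::rnorm(60, 0, 0.01)
  )
  X2$B <- base$a + 0.3 * y # strongest outcome link
  flt2 <- filter_correlated(X2, y)
  expect_identical(flt2$kept, "B")
  expect_equal(nrow(flt2$dropped), 2L)
  expect_true(all(flt2$dropped$kept == "B"))
  # independent columns pass through unchanged
  flt3 <- filter_correlated(base, y)
  expect_identical(flt3$kept, names(base))
  # constant predictors are logged, not fatal
  X4 <- dplyr::mutate(base, const = 1)
  flt4 <- filter_correlated(X4, y)
  expect_true("const" %in% flt4$constant)
})

test_that("mean log loss matches its closed forms and a hand fixture", {
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(mean_log_loss(onehot, c(0, 1, 2, 0)), 0, tolerance = 1e-10)
  unif <- matrix(1 / 3, 4, 3)
  expect_equal(mean_log_loss(unif, c(0, 1, 2, 0)), log(3), tolerance = 1e-12)
  p <- rbind(
    c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1),
    c(0.2, 0.3, 0.5), c(0.6, 0.3, 0.1)
  )
  ref <- -(log(0.7) + log(0.8) + log(0.5) + log(0.6)) / 4
  expect_equal(mean_log_loss(p, c(0, 1, 2, 0)), ref, tolerance = 1e-12)
  bad <- rbind(c(0.5, 0.2, 0.1))
  expect_error(mean_log_loss(bad, 0), class = "prosodia_argument_error")
})

test_that("space-filling candidates respect the tuning-grid bounds", {
  for (kind in c("svm_poly", "ordinal_elasticnet", "random_forest", "knn")) {
    cand <- space_filling_candidates(kind, 40, seed = 2)
    expect_equal(nrow(cand), 40L)
    if (kind == "svm_poly") {
      expect_true(all(cand$cost >= 9.96e-4 & cand$cost <= 31.6))
    }
    if (kind == "ordinal_elasticnet") {
      expect_true(all(cand$lambda >= 0 & cand$lambda <= 0.998))
      expect_true(all(cand$alpha >= 6.7e-4 & cand$alpha <= 0.999))
    }
    if (kind == "random_forest") {
      expect_true(all(cand$num_trees >= 1 & cand$num_trees <= 2000))
      expect_true(all(cand$mtry >= 1 & cand$mtry <= 74))
      expect_true(all(cand$min_node >= 2 & cand$min_node <= 40))
    }
    if (kind == "knn") {
      expect_true(all(cand$k >= 1 & cand$k <= 15))
      expect_true(all(cand$kernel %in% c(
        "rectangular", "triangular", "epanechnikov", "biweight",
        "triweight", "cos", "inversion", "gaussian", "rank"
      )))
      expect_true(all(cand$minkowski_p >= 1 & cand$minkowski_p <= 2))
    }
  }
  # maximin design spreads at least as well as a plain uniform draw
  U <- prosodia:::.with_seed(5, lhs::maximinLHS(20, 2))
  R <- prosodia:::.with_seed(5, matrix(stats::runif(40), 20, 2))
  min_d <- function(M) min(stats::dist(M))
  expect_gte(min_d(U), min_d(R))
})

test_that("every learner emits valid simplex probabilities", {
  bd <- make_blob_data()
  cands <- list(
    svm_poly = tibble::tibble(cost = 1),
    ordinal_elasticnet = tibble::tibble(lambda = 0.01, alpha = 0.5),
    random_forest = tibble::tibble(num_trees = 100L, mtry = 3L, min_node = 5L),
    knn = tibble::tibble(k = 7L, kernel = "triangular", minkowski_p = 2)
  )
  for (kind in names(cands)) {
    m <- fit_learner(kind, bd$X, bd$y, cands[[kind]], seed = 1)
    p <- predict_probs(m, bd$X)
    expect_true(all(p >= 0), info = kind)
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
    # separable blobs: all learners clearly beat chance
    expect_lt(mean_log_loss(p, bd$y), log(3))
  }
})

test_that("cross-validated tuning is deterministic and beats chance", {
  bd <- make_blob_data(n_per_class = 20)
  tc <- tune_cv("random_forest", bd$X, bd$y, n_candidates = 5, k = 10, seed = 2)
  expect_lt(tc$cv_loss, log(3))
  expect_equal(tc$cv_loss, mean(tc$fold_losses), tolerance = 1e-12)
  expect_length(tc$fold_models, 10L)
  tc2 <- tune_cv("random_forest", bd$X, bd$y, n_candidates = 5, k = 10, seed = 2)
  expect_identical(tc$best_params, tc2$best_params)
  expect_equal(tc$cv_loss, tc2$cv_loss)
  # bounds invariant: the chosen candidate is inside the tuning grid
  expect_true(tc$best_params$num_trees >= 1 && tc$best_params$num_trees <= 2000)
  expect_true(tc$best_params$min_node >= 2 && tc$best_params$min_node <= 40)
})

fake_model <- function(probs_fun, features = c("x1", "x2")) {
  structure(
    list(kind = "random_forest", params = list(), features = features,
      predict_fun = probs_fun),
    class = "prosodia_model"
  )
}

test_that("fold averaging is the arithmetic mean of probabilities", {
  m1 <- fake_model(function(X) matrix(rep(c(1, 0, 0), each = nrow(X)), ncol = 3))
  m2 <- fake_model(function(X) matrix(rep(c(0, 1, 0), each = nrow(X)), ncol = 3))
  avg <- average_fold_models(list(m1, m2))
  p <- predict_probs(avg, data.frame(x1 = 1:3, x2 = 1:3))
  expect_equal(unname(p), matrix(rep(c(0.5, 0.5, 0), each = 3), ncol = 3))
  same <- average_fold_models(list(m1, m1, m1))
  ps <- predict_probs(same, data.frame(x1 = 1:2, x2 = 1:2))
  expect_equal(unname(ps), matrix(rep(c(1, 0, 0), each = 2), ncol = 3))
  expect_equal(rowSums(p), c(1, 1, 1))
  expect_error(average_fold_models(list(m1)), class = "prosodia_argument_error")
  m3 <- fake_model(function(X) matrix(1 / 3, nrow(X), 3))
  m3$kind <- "knn"
  expect_error(average_fold_models(list(m1, m3)), class = "prosodia_argument_error")
})

test_that("stacking weighs the stronger base model higher", {
  n <- 90
  y <- rep(0:2, each = 30)
  good <- 0.90 * diag(3)[y + 1, ] + 0.10 / 3
  bad <- matrix(1 / 3, n, 3)
  bad[cbind(1:n, ((y + 1) %% 3) + 1)] <- 0.5 # systematically wrong
  bad <- bad / rowSums(bad)
  mg <- fake_model(function(X) good[seq_len(nrow(X)), ])
  mb <- fake_model(function(X) bad[seq_len(nrow(X)), ])
  ens <- stack_ensemble(
    list(good = mg, bad = mb),
    list(good = good, bad = bad), y
  )
  expect_gt(ens$weights[["good"]], ens$weights[["bad"]])
  expect_gt(ens$weights[["good"]], 0.5)
  p <- predict_probs(ens, data.frame(x1 = 1:n, x2 = 1:n))
  expect_equal(rowSums(p), rep(1, n), tolerance = 1e-9)
  # identical base models: the ensemble equals any one of them
  ens2 <- stack_ensemble(list(a = mg, b = mg), list(a = good, b = good), y)
  p2 <- predict_probs(ens2, data.frame(x1 = 1:n, x2 = 1:n))
  expect_equal(unname(p2), unname(good), tolerance = 1e-6)
})

test_that("FIRM importance isolates the predictors a model uses", {
  # linear scorer: softmax over class scores from w . x
  w <- c(3, -2, 1, 0, 0.5)
  p <- length(w)
  X <- withr::with_seed(17, {
    M <- matrix(stats::rnorm(200 * p), 200, p)
    M[, 3] <- M[, 3] * 4 # larger spread amplifies importance
    colnames(M) <- paste0("f", 1:p)
    as.data.frame(M)
  })
  scorer <- function(M) {
    s <- as.matrix(M) %*% w
    z <- cbind(-s, 0 * s, s)
    exp(z) / rowSums(exp(z))
  }
  imp <- firm_importance(scorer, X)
  expect_true(all(imp$importance >= 0))
  expect_equal(imp$importance[imp$feature == "f4"], 0, tolerance = 1e-9)
  # rank order matches |w_j| * sd(x_j)
  target <- abs(w) * apply(X, 2, stats::sd)
  got <- imp$importance[match(paste0("f", 1:p), imp$feature)]
  expect_equal(order(got, decreasing = TRUE), order(target, decreasing = TRUE))
  # doubling a predictor scale while halving its weight leaves FIRM put
  w2 <- w
  w2[1] <- w[1] / 2
  X2 <- X
  X2[, 1] <- X[, 1] * 2
  scorer2 <- function(M) {
    s <- as.matrix(M) %*% w2
    z <- cbind(-s, 0 * s, s)
    exp(z) / rowSums(exp(z))
  }
  imp2 <- firm_importance(scorer2, X2)
  i1 <- imp$importance[imp$feature == "f1"]
  i2 <- imp2$importance[imp2$feature == "f1"]
  expect_lt(abs(i2 - i1) / i1, 0.02)
})

test_that("the f0-variability baseline is ordinal and deterministic", {
  d <- withr::with_seed(23, {
    n <- 120
    x <- stats::runif(n, 0, 10)
    y <- pmin(2, pmax(0, round(2 - x / 5 + stats::rnorm(n, 0, 0.3))))
    tibble::tibble(mtp_f0_sd = x, severity = y)
  })
  m <- baseline_f0sd_model(d, d$severity)
  grid <- tibble::tibble(mtp_f0_sd = c(0.5, 5, 9.5))
  pred <- predict(m, grid, type = "class")
  expect_true(all(diff(pred) <= 0)) # monotone: higher f0 SD, lower severity here
  m2 <- baseline_f0sd_model(d, d$severity)
  expect_equal(predict_probs(m, grid), predict_probs(m2, grid))
})
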