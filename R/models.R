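#' Recording-level stratified train/test split
#'
#' Splits at the recording level (all utterances of one recording land on
#' the same side) with per-class test proportions matching the global test
#' fraction up to rounding.
#'
#' @param data Tibble with one row per utterance.
#' @param test_fraction Fraction of recordings per class sent to the test
#'   side (default 0.25).
#' @param seed Integer seed.
#' @param group_col Column identifying the recording (default
#'   `"recording_id"`). Pass `"speaker_id"` to hold out whole speakers.
#' @param label_col Severity label column (default `"severity"`).
#' @return List with `train` and `test` tibbles.
#' @export
stratified_split <- function(data, test_fraction = 0.25, seed = 1L,
                             group_col = "recording_id", label_col = "severity") {
  recs <- dplyr::distinct(data, .data[[group_col]], .data[[label_col]])
  if (anyDuplicated(recs[[group_col]])) {
    rlang::abort("A recording maps to more than one label.", class = "prosodia_argument_error")
  }
  counts <- table(recs[[label_col]])
  if (any(counts < 4)) {
    rlang::abort("Each class needs at least 4 recordings.", class = "prosodia_argument_error")
  }
  test_ids <- .with_seed(seed, {
    unlist(lapply(split(recs[[group_col]], recs[[label_col]]), function(ids) {
      n_test <- max(1L, round(length(ids) * test_fraction))
      sample(ids, n_test)
    }), use.names = FALSE)
  })
  list(
    train = data[!data[[group_col]] %in% test_ids, ],
    test = data[data[[group_col]] %in% test_ids, ]
  )
}

#' Screen out highly correlated predictors
#'
#' Builds a graph over predictor pairs with `|Spearman rho| >
#' rho_threshold`; within each connected component only the predictor with
#' the highest absolute Spearman correlation with the outcome survives.
#' Constant predictors have undefined correlations, treated as 0 and
#' logged.
#'
#' @param X Data frame of numeric predictors.
#' @param y Ordinal outcome (integer codes).
#' @param rho_threshold Correlation threshold (default 0.9).
#' @return List: `data` (reduced predictor frame), `kept`, `dropped`
#'   (tibble mapping each dropped predictor to its surviving substitute).
#' @export
filter_correlated <- function(X, y, rho_threshold = 0.9) {
  Xm <- as.matrix(X)
  p <- ncol(Xm)
  ranks <- apply(Xm, 2, rank, ties.method = "average")
  const <- apply(ranks, 2, stats::sd) == 0
  cm <- suppressWarnings(stats::cor(ranks))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  ry <- rank(y, ties.method = "average")
  ycor <- suppressWarnings(as.numeric(stats::cor(ranks, ry)))
  ycor[!is.finite(ycor)] <- 0
  # connected components of the |rho| > threshold graph (union-find)
  parent <- seq_len(p)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  hits <- which(abs(cm) > rho_threshold, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  for (r in seq_len(nrow(hits))) {
    a <- find(hits[r, 1]); b <- find(hits[r, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(p), find, integer(1))
  keep <- logical(p)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    keep[members[which.max(abs(ycor[members]))]] <- TRUE
  }
  nm <- colnames(Xm)
  dropped <- tibble::tibble(
    dropped = nm[!keep],
    kept = vapply(which(!keep), function(j) {
      members <- which(comp == comp[j])
      nm[members[which.max(abs(ycor[members]))]]
    }, character(1))
  )
  list(
    data = tibble::as_tibble(X)[, keep, drop = FALSE],
    kept = nm[keep],
    dropped = dropped,
    constant = nm[const]
  )
}

#' Mean logarithmic loss
#'
#' `-(1/n) * sum(ln p(true class))` with probabilities clipped to
#' `[1e-15, 1]`.
#'
#' @param probs Matrix/data frame of class probabilities, columns in class
#'   order 0, 1, 2; rows must sum to 1 within 1e-6.
#' @param truth Integer labels in `{0, 1, 2}`.
#' @return Non-negative scalar.
#' @export
mean_log_loss <- function(probs, truth) {
  p <- as.matrix(probs)
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    rlang::abort("Probability rows must sum to 1.", class = "prosodia_argument_error")
  }
  pt <- p[cbind(seq_along(truth), as.integer(truth) + 1L)]
  -mean(log(pmin(pmax(pt, 1e-15), 1)))
}

.knn_kernels <- c(
  "rectangular", "triangular", "epanechnikov", "biweight",
  "triweight", "cos", "inversion", "gaussian", "rank"
)

# Hyperparameter ranges of the tuning grid, one block per model kind.
.param_defs <- function(kind, p_max = 74L) {
  switch(kind,
    svm_poly = list(
      cost = list(lo = 9.96e-4, hi = 31.6, scale = "log")
    ),
    ordinal_elasticnet = list(
      lambda = list(lo = 0, hi = 0.998, scale = "sqr"),
      alpha = list(lo = 6.7e-4, hi = 0.999, scale = "log")
    ),
    random_forest = list(
      num_trees = list(lo = 1, hi = 2000, scale = "int"),
      mtry = list(lo = 1, hi = p_max, scale = "int"),
      min_node = list(lo = 2, hi = 40, scale = "int")
    ),
    knn = list(
      k = list(lo = 1, hi = 15, scale = "int"),
      kernel = list(levels = .knn_kernels, scale = "cat"),
      minkowski_p = list(lo = 1, hi = 2, scale = "lin")
    ),
    rlang::abort(sprintf("Unknown model kind '%s'.", kind), class = "prosodia_argument_error")
  )
}

#' Space-filling hyperparameter candidates
#'
#' Maximin Latin-hypercube design over the tuning ranges of the requested
#' model kind (log scale for the SVM cost and the elastic-net mixing
#' parameter; integer rounding for counts; the nine kNN kernels sampled as
#' a categorical dimension).
#'
#' @param kind One of `"svm_poly"`, `"ordinal_elasticnet"`,
#'   `"random_forest"`, `"knn"`.
#' @param n Number of candidates (default 1000; cross-validation tests use
#'   far fewer).
#' @param seed Integer seed.
#' @param p_max Upper bound for the predictors-per-split dimension
#'   (capped at the number of available predictors at fit time).
#' @return Tibble of candidate hyperparameter settings.
#' @export
space_filling_candidates <- function(kind, n = 1000L, seed = 1L, p_max = 74L) {
  defs <- .param_defs(kind, p_max = p_max)
  d <- length(defs)
  U <- .with_seed(seed, lhs::maximinLHS(as.integer(n), d))
  out <- purrr::imap(defs, function(def, nm) {
    u <- U[, match(nm, names(defs))]
    switch(def$scale,
      log = exp(log(def$lo) + u * (log(def$hi) - log(def$lo))),
      lin = def$lo + u * (def$hi - def$lo),
      sqr = def$lo + u^2 * (def$hi - def$lo),
      int = as.integer(round(def$lo + u * (def$hi - def$lo))),
      cat = def$levels[pmin(length(def$levels), 1L + floor(u * length(def$levels)))]
    )
  })
  tibble::as_tibble(out)
}

# ---- learners ---------------------------------------------------------------

.standardizer <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(mu = mu, sg = sg, apply = function(M) sweep(sweep(M, 2, mu), 2, sg, "/"))
}

.fix_probs <- function(p) {
  p[!is.finite(p)] <- 0
  p <- pmax(p, 0)
  s <- rowSums(p)
  bad <- s <= 0
  p[bad, ] <- 1 / ncol(p)
  s[bad] <- 1
  p / s
}

# Penalized proportional-odds (ordinal elastic-net) fitted by BFGS with a
# smoothed L1 term: objective = NLL/n + lambda * (alpha * |b|_1 + (1-alpha)/2 |b|_2^2).
.fit_ordinal_en <- function(X, y, lambda, alpha, maxit = 200L) {
  std <- .standardizer(X)
  Z <- std$apply(X)
  n <- nrow(Z); p <- ncol(Z)
  y <- as.integer(y)
  eps <- 1e-8
  cum <- pmin(pmax(cumsum(table(factor(y, 0:2)))[1:2] / n, 1e-3), 1 - 1e-3)
  init <- c(stats::qlogis(cum[1]), log(max(stats::qlogis(cum[2]) - stats::qlogis(cum[1]), 0.1)),
            numeric(p))
  obj <- function(par) {
    t1 <- par[1]; t2 <- t1 + exp(par[2]); b <- par[-(1:2)]
    eta <- as.numeric(Z %*% b)
    g1 <- stats::plogis(t1 - eta); g2 <- stats::plogis(t2 - eta)
    pr <- cbind(g1, g2 - g1, 1 - g2)
    pt <- pmax(pr[cbind(1:n, y + 1L)], 1e-12)
    nll <- -sum(log(pt)) / n
    nll + lambda * (alpha * sum(sqrt(b^2 + eps)) + (1 - alpha) / 2 * sum(b^2))
  }
  grad <- function(par) {
    t1 <- par[1]; t2 <- t1 + exp(par[2]); b <- par[-(1:2)]
    eta <- as.numeric(Z %*% b)
    g1 <- stats::plogis(t1 - eta); g2 <- stats::plogis(t2 - eta)
    d1 <- g1 * (1 - g1); d2 <- g2 * (1 - g2)
    pr <- cbind(g1, g2 - g1, 1 - g2)
    pt <- pmax(pr[cbind(1:n, y + 1L)], 1e-12)
    # d log p / d t1, t2, eta per row
    dt1 <- ifelse(y == 0L, d1 / pt, ifelse(y == 1L, -d1 / pt, 0))
    dt2 <- ifelse(y == 1L, d2 / pt, ifelse(y == 2L, -d2 / pt, 0))
    deta <- ifelse(y == 0L, -d1 / pt, ifelse(y == 1L, (d1 - d2) / pt, d2 / pt))
    gt1 <- -sum(dt1 + dt2) / n
    ggam <- -sum(dt2) / n * exp(par[2])
    gb <- -as.numeric(crossprod(Z, deta)) / n +
      lambda * (alpha * b / sqrt(b^2 + eps) + (1 - alpha) * b)
    c(gt1, ggam, gb)
  }
  fit <- stats::optim(init, obj, grad, method = "BFGS", control = list(maxit = maxit))
  list(par = fit$par, std = std,
    predict = function(newX) {
      Zn <- std$apply(as.matrix(newX))
      t1 <- fit$par[1]; t2 <- t1 + exp(fit$par[2]); b <- fit$par[-(1:2)]
      eta <- as.numeric(Zn %*% b)
      g1 <- stats::plogis(t1 - eta); g2 <- stats::plogis(t2 - eta)
      .fix_probs(cbind(g1, g2 - g1, 1 - g2))
    })
}

# Kernel-weighted k-nearest-neighbour class probabilities.
.fit_knn <- function(X, y, k, kernel, minkowski_p) {
  std <- .standardizer(X)
  Z <- std$apply(X)
  y <- as.integer(y)
  kern_w <- function(u, d) {
    switch(kernel,
      rectangular = rep(1, length(u)),
      triangular = pmax(1 - u, 0),
      epanechnikov = pmax(0.75 * (1 - u^2), 0),
      biweight = pmax(15 / 16 * (1 - u^2)^2, 0),
      triweight = pmax(35 / 32 * (1 - u^2)^3, 0),
      cos = ifelse(u < 1, pi / 4 * cos(pi * u / 2), 0),
      inversion = 1 / pmax(d, 1e-9),
      gaussian = stats::dnorm(u),
      rank = rev(seq_along(u)) / sum(seq_along(u))
    )
  }
  list(std = std,
    predict = function(newX) {
      Zn <- std$apply(as.matrix(newX))
      out <- matrix(0, nrow(Zn), 3L)
      kk <- min(k, nrow(Z) - 1L)
      for (i in seq_len(nrow(Zn))) {
        dv <- (rowSums(abs(sweep(Z, 2, Zn[i, ]))^minkowski_p))^(1 / minkowski_p)
        o <- order(dv)[seq_len(kk + 1L)]
        dk <- dv[o]
        u <- dk[seq_len(kk)] / max(dk[kk + 1L], 1e-9)
        w <- kern_w(pmin(u, 1 - 1e-9), dk[seq_len(kk)])
        if (sum(w) <= 0) w <- rep(1, kk)
        for (cl in 0:2) out[i, cl + 1L] <- sum(w[y[o[seq_len(kk)]] == cl])
      }
      .fix_probs(out)
    })
}

#' Fit a single severity learner
#'
#' @param kind `"svm_poly"`, `"ordinal_elasticnet"`, `"random_forest"` or
#'   `"knn"`.
#' @param X Data frame/matrix of predictors.
#' @param y Integer severity labels in `{0, 1, 2}`.
#' @param params One-row tibble/list of hyperparameters (see
#'   [space_filling_candidates()]).
#' @param seed Integer seed (tree learners).
#' @return A `prosodia_model` with a class-probability predictor.
#' @export
fit_learner <- function(kind, X, y, params, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  fit <- switch(kind,
    svm_poly = {
      std <- .standardizer(X)
      Z <- std$apply(X)
      m <- .with_seed(seed, e1071::svm(Z, factor(y, 0:2),
        kernel = "polynomial", degree = 3, coef0 = 1,
        cost = params$cost, probability = TRUE, scale = FALSE
      ))
      list(predict = function(newX) {
        Zn <- std$apply(as.matrix(newX))
        pr <- attr(stats::predict(m, Zn, probability = TRUE), "probabilities")
        .fix_probs(pr[, as.character(0:2), drop = FALSE])
      })
    },
    ordinal_elasticnet = .fit_ordinal_en(X, y, params$lambda, params$alpha),
    random_forest = {
      df <- data.frame(y = factor(y, 0:2), X)
      m <- ranger::ranger(y ~ ., df,
        num.trees = max(1L, params$num_trees),
        mtry = min(params$mtry, ncol(X)),
        min.node.size = params$min_node,
        probability = TRUE, seed = seed, num.threads = 1
      )
      list(predict = function(newX) {
        pr <- stats::predict(m,
          data.frame(as.matrix(newX)), num.threads = 1
        )$predictions
        .fix_probs(pr[, as.character(0:2), drop = FALSE])
      })
    },
    knn = .fit_knn(X, y, params$k, params$kernel, params$minkowski_p),
    rlang::abort(sprintf("Unknown model kind '%s'.", kind), class = "prosodia_argument_error")
  )
  structure(
    list(kind = kind, params = params, predict_fun = fit$predict,
      features = colnames(X)),
    class = "prosodia_model"
  )
}

#' Class probabilities from a fitted model
#'
#' @param object A `prosodia_model`.
#' @param newdata Data frame/matrix of predictors (must contain the
#'   model's feature columns).
#' @param ... Unused.
#' @return Matrix of class probabilities (columns: severity 0, 1, 2);
#'   rows sum to 1.
#' @export
predict_probs <- function(object, newdata, ...) {
  if (is.function(object)) return(.fix_probs(object(newdata)))
  stopifnot(inherits(object, "prosodia_model"))
  nd <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  p <- object$predict_fun(nd)
  colnames(p) <- .severity_levels
  p
}

#' @export
predict.prosodia_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_probs(object, newdata)
  if (type == "prob") return(p)
  as.integer(max.col(p) - 1L)
}

#' @export
print.prosodia_model <- function(x, ...) {
  cat(sprintf("<prosodia_model: %s, %d features>\n", x$kind, length(x$features)))
  invisible(x)
}

# Stratified fold assignment; re-stratifies once if a training side would
# miss a class.
.make_folds <- function(y, k, seed) {
  assign_once <- function(s) {
    .with_seed(s, {
      fold <- integer(length(y))
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep(seq_len(k), length.out = length(idx))
      }
      fold
    })
  }
  fold <- assign_once(seed)
  ok <- all(vapply(seq_len(k), function(f) {
    length(unique(y[fold != f])) == length(unique(y))
  }, logical(1)))
  if (!ok) {
    fold <- assign_once(seed + 1L)
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[fold != f])) == length(unique(y))
    }, logical(1)))
    if (!ok) {
      rlang::abort("Could not stratify folds: a class is too small.",
        class = "prosodia_argument_error"
      )
    }
  }
  fold
}

#' Cross-validated hyperparameter tuning
#'
#' 10-fold stratified cross-validation over space-filling candidates: each
#' candidate is scored by the mean holdout log loss across folds; the best
#' candidate is refit on each fold's training part, yielding the ten fold
#' models that are later averaged.
#'
#' @param kind Model kind (see [fit_learner()]).
#' @param X Predictor frame.
#' @param y Integer severity labels.
#' @param n_candidates Number of space-filling candidates.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List with `kind`, `best_params`, `cv_loss`, `fold_losses`,
#'   `fold_models`, `oof_probs` (out-of-fold probabilities under the best
#'   candidate), `fold` (assignments), `candidates` (with their losses).
#' @export
tune_cv <- function(kind, X, y, n_candidates = 1000L, k = 10L, seed = 1L) {
  y <- as.integer(y)
  if (length(y) < 10L * length(unique(y))) {
    rlang::abort("Too few rows for 10-fold tuning.", class = "prosodia_argument_error")
  }
  cand <- space_filling_candidates(kind, n_candidates, seed, p_max = 74L)
  fold <- .make_folds(y, k, seed)
  Xm <- as.matrix(X)
  losses <- matrix(NA_real_, nrow(cand), k)
  for (ci in seq_len(nrow(cand))) {
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- fit_learner(kind, Xm[tr, , drop = FALSE], y[tr], cand[ci, ],
        seed = seed + f
      )
      p <- predict_probs(m, Xm[!tr, , drop = FALSE])
      losses[ci, f] <- mean_log_loss(p, y[!tr])
    }
  }
  mean_loss <- rowMeans(losses)
  best <- which.min(mean_loss)
  fold_models <- lapply(seq_len(k), function(f) {
    fit_learner(kind, Xm[fold != f, , drop = FALSE], y[fold != f],
      cand[best, ],
      seed = seed + f
    )
  })
  oof <- matrix(NA_real_, length(y), 3L)
  for (f in seq_len(k)) {
    oof[fold == f, ] <- predict_probs(fold_models[[f]], Xm[fold == f, , drop = FALSE])
  }
  list(
    kind = kind, best_params = cand[best, ],
    cv_loss = mean_loss[best], fold_losses = losses[best, ],
    fold_models = fold_models, oof_probs = oof, fold = fold,
    candidates = dplyr::mutate(cand, cv_loss = mean_loss)
  )
}

#' Average fold models into a final model
#'
#' The final model of each kind predicts the arithmetic mean of its ten
#' fold models' class probabilities.
#'
#' @param fold_models List of `prosodia_model` objects of one kind.
#' @return A `prosodia_model` of the same kind.
#' @export
average_fold_models <- function(fold_models) {
  if (length(fold_models) < 2L) {
    rlang::abort("Need at least 2 fold models.", class = "prosodia_argument_error")
  }
  kinds <- unique(vapply(fold_models, function(m) m$kind, character(1)))
  if (length(kinds) != 1L) {
    rlang::abort("Fold models must all be of the same kind.",
      class = "prosodia_argument_error"
    )
  }
  feats <- fold_models[[1]]$features
  structure(
    list(
      kind = kinds, params = fold_models[[1]]$params, features = feats,
      predict_fun = function(newX) {
        ps <- lapply(fold_models, function(m) m$predict_fun(as.matrix(newX)))
        Reduce(`+`, ps) / length(ps)
      }
    ),
    class = "prosodia_model"
  )
}

#' Stack base models into a weighted ensemble
#'
#' Learns non-negative weights (summing to one) over the base models by
#' minimizing the log loss of the weighted probability combination on
#' out-of-fold predictions, so each base model is weighed by its strength
#' on data it did not see during fitting.
#'
#' @param final_models Named list of final (fold-averaged)
#'   `prosodia_model`s.
#' @param oof_list Named list of out-of-fold probability matrices, one per
#'   base model, aligned with `y`.
#' @param y Integer severity labels for the out-of-fold rows.
#' @return A `prosodia_model` of kind `"ensemble"`; field `weights` holds
#'   the learned base-model weights.
#' @export
stack_ensemble <- function(final_models, oof_list, y) {
  if (length(final_models) < 2L) {
    rlang::abort("Need at least 2 base models.", class = "prosodia_argument_error")
  }
  stopifnot(identical(names(final_models), names(oof_list)))
  m <- length(oof_list)
  y <- as.integer(y)
  mix <- function(theta) {
    w <- exp(theta - max(theta))
    w / sum(w)
  }
  loss <- function(theta) {
    w <- mix(theta)
    P <- Reduce(`+`, Map(`*`, oof_list, w))
    mean_log_loss(.fix_probs(P), y)
  }
  fit <- tryCatch(
    stats::optim(numeric(m), loss, method = "BFGS", control = list(maxit = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    w <- rep(1 / m, m)
    flagged <- TRUE
  } else {
    w <- mix(fit$par)
    flagged <- FALSE
  }
  names(w) <- names(final_models)
  feats <- final_models[[1]]$features
  structure(
    list(
      kind = "ensemble", weights = w, features = feats, flagged = flagged,
      predict_fun = function(newX) {
        ps <- Map(
          function(mod, wi) wi * mod$predict_fun(as.matrix(newX)),
          final_models, w
        )
        .fix_probs(Reduce(`+`, ps))
      }
    ),
    class = "prosodia_model"
  )
}

#' Feature importance ranking measure (FIRM)
#'
#' For each predictor its values are split into `bins` quantile bins; the
#' model's mean class probabilities are computed with the predictor
#' clamped to each bin's median, and the importance is the standard
#' deviation (root mean squared change) of that conditional expectation
#' across bins, averaged over the three classes. Predictors the model
#' ignores score 0.
#'
#' @param model A `prosodia_model`, or a function mapping a predictor
#'   matrix to class probabilities.
#' @param X Reference predictor frame (the feature distribution).
#' @param bins Number of quantile bins (default 10).
#' @return An `importance_table` tibble (`feature`, `importance`), sorted
#'   decreasing.
#' @export
firm_importance <- function(model, X, bins = 10L) {
  Xm <- as.matrix(X)
  pred <- function(M) {
    if (is.function(model)) .fix_probs(model(M)) else predict_probs(model, M)
  }
  imp <- vapply(seq_len(ncol(Xm)), function(j) {
    v <- Xm[, j]
    if (stats::sd(v) == 0) return(0)
    edges <- unique(stats::quantile(v, seq(0, 1, length.out = bins + 1L), type = 7))
    if (length(edges) < 3L) return(0)
    bin <- cut(v, edges, include.lowest = TRUE, labels = FALSE)
    meds <- vapply(seq_len(max(bin)), function(b) stats::median(v[bin == b]), numeric(1))
    q <- vapply(meds, function(mv) {
      M <- Xm
      M[, j] <- mv
      colMeans(pred(M))
    }, numeric(3))
    # population SD across bins, averaged over classes
    mean(apply(q, 1, function(r) sqrt(mean((r - mean(r))^2))))
  }, numeric(1))
  out <- tibble::tibble(feature = colnames(Xm), importance = imp)
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  class(out) <- c("importance_table", class(out))
  out
}

#' Ordinal baseline using only utterance-wide f0 variability
#'
#' Proportional-odds logistic regression with the f0 standard-deviation
#' predictor as its single input -- the literature's predominant
#' dysprosody proxy, used as a comparison baseline.
#'
#' @param data Tibble containing the predictor column and labels.
#' @param y Integer severity labels.
#' @param predictor Name of the f0-variability column (default
#'   `"mtp_f0_sd"`).
#' @return A `prosodia_model` of kind `"f0sd_baseline"`.
#' @export
baseline_f0sd_model <- function(data, y, predictor = "mtp_f0_sd") {
  x <- data[[predictor]]
  stopifnot(!is.null(x))
  df <- data.frame(y = factor(as.integer(y), 0:2, ordered = TRUE), x = x)
  m <- MASS::polr(y ~ x, data = df, method = "logistic", Hess = FALSE)
  structure(
    list(
      kind = "f0sd_baseline", params = list(predictor = predictor),
      features = predictor,
      predict_fun = function(newX) {
        nd <- data.frame(x = as.matrix(newX)[, 1])
        .fix_probs(unname(as.matrix(stats::predict(m, nd, type = "probs"))))
      }
    ),
    class = "prosodia_model"
  )
}

#' Train the full severity model set
#'
#' Median-imputes missing predictor cells, screens correlated predictors,
#' tunes each requested learner by cross-validation, averages the fold
#' models, stacks the final models into an ensemble, and (optionally)
#' computes FIRM importances for the best base model.
#'
#' @param features Tibble with the predictor columns of [feature_names()]
#'   plus a `severity` label column.
#' @param kinds Learner kinds to tune (default all four).
#' @param n_candidates Space-filling candidates per learner.
#' @param k Folds (default 10).
#' @param seed Integer seed.
#' @param compute_importance Compute FIRM for the best model
#'   (default TRUE).
#' @param label_col Name of the label column.
#' @return A `severity_model_set`: list with `models` (named, incl.
#'   `ensemble`), `tuned` (per-kind tuning results), `best_kind`,
#'   `importance`, `filter` (correlation-screen log), `medians`
#'   (imputation values), `feature_checksum`.
#' @export
train_severity_models <- function(features,
                                  kinds = c(
                                    "svm_poly", "ordinal_elasticnet",
                                    "random_forest", "knn"
                                  ),
                                  n_candidates = 25L, k = 10L, seed = 1L,
                                  compute_importance = TRUE,
                                  label_col = "severity") {
  y <- as.integer(features[[label_col]])
  pred_cols <- intersect(feature_names(), names(features))
  X <- features[, pred_cols]
  medians <- vapply(X, function(v) stats::median(v[is.finite(v)]), numeric(1))
  medians[!is.finite(medians)] <- 0
  for (cn in names(X)) {
    v <- X[[cn]]
    v[!is.finite(v)] <- medians[[cn]]
    X[[cn]] <- v
  }
  flt <- filter_correlated(X, y)
  Xr <- flt$data
  tuned <- lapply(kinds, function(kd) {
    tune_cv(kd, Xr, y, n_candidates = n_candidates, k = k, seed = seed)
  })
  names(tuned) <- kinds
  models <- lapply(tuned, function(tc) average_fold_models(tc$fold_models))
  ens <- stack_ensemble(models, lapply(tuned, function(tc) tc$oof_probs), y)
  best_kind <- kinds[which.min(vapply(tuned, function(tc) tc$cv_loss, numeric(1)))]
  importance <- NULL
  if (compute_importance) {
    importance <- firm_importance(models[[best_kind]], Xr)
  }
  structure(
    list(
      models = c(models, list(ensemble = ens)), tuned = tuned,
      best_kind = best_kind, importance = importance, filter = flt,
      medians = medians, features = names(Xr),
      feature_checksum = feature_checksum()
    ),
    class = "severity_model_set"
  )
}

#' Prepare a feature table for prediction with a trained model set
#'
#' Applies the training-time imputation and column selection.
#'
#' @param model_set A `severity_model_set`.
#' @param features Feature tibble.
#' @return Predictor matrix aligned with the model set.
#' @export
prepare_features <- function(model_set, features) {
  X <- features[, names(model_set$medians)]
  for (cn in names(X)) {
    v <- X[[cn]]
    v[!is.finite(v)] <- model_set$medians[[cn]]
    X[[cn]] <- v
  }
  as.matrix(X[, model_set$features])
}

#' Evaluate a model on labelled features
#'
#' @param model A `prosodia_model`.
#' @param X Predictor matrix/frame.
#' @param y Integer severity labels.
#' @return List with `confusion` ([confusion_matrix()]), `report`
#'   ([macro_ovr_report()]), `log_loss`, and the probability matrix.
#' @export
evaluate_model <- function(model, X, y) {
  p <- predict_probs(model, X)
  pred <- as.integer(max.col(p) - 1L)
  cm <- confusion_matrix(as.integer(y), pred)
  list(
    confusion = cm, report = macro_ovr_report(cm),
    log_loss = mean_log_loss(p, as.integer(y)), probs = p
  )
}

#' @export
#' @method tidy severity_model_set
tidy.severity_model_set <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$tuned), function(kd) {
    tc <- x$tuned[[kd]]
    tibble::tibble(
      kind = kd, fold = seq_along(tc$fold_losses),
      log_loss = tc$fold_losses
    )
  }))
}

#' @export
#' @method glance severity_model_set
glance.severity_model_set <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$tuned), function(kd) {
    tibble::tibble(kind = kd, cv_loss = x$tuned[[kd]]$cv_loss)
  }))
}
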