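# ---- regressor registry ---------------------------------------------------
#
# Twelve algorithm families behind one fit/predict contract, mirroring the
# usual QSAR benchmarking spread: five linear-family models (OLS, ridge,
# kernel ridge, SGD-fitted linear, linear SVR), three tree ensembles
# (random forest, gradient boosting, AdaBoost.R2), a single decision tree,
# a multilayer perceptron, an RBF-kernel SVR and k-nearest neighbors.
# Only glmnet is available as an external solver, so the remaining learners
# are implemented here directly; the two SVR variants use a smoothed
# (huberized) epsilon-insensitive loss minimized with L-BFGS-B, which keeps
# them deterministic and dependency-free.

ww_fit <- function(predict_fun, info = NULL) {
  structure(list(predict_fun = predict_fun, info = info), class = "ww_fit")
}

#' @export
predict.ww_fit <- function(object, newdata, ...) {
  object$predict_fun(as_feature_matrix(newdata))
}

std_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(ctr = ctr, scl = scl)
}
std_apply <- function(X, s) sweep(sweep(X, 2, s$ctr), 2, s$scl, "/")

# smoothed epsilon-insensitive loss and its derivative wrt the residual
eps_loss <- function(r, eps, h) {
  t <- pmax(abs(r) - eps, 0)
  ifelse(t <= h, t^2 / (2 * h), t - h / 2)
}
eps_grad <- function(r, eps, h) {
  t <- pmax(abs(r) - eps, 0)
  sign(r) * pmin(t / h, 1)
}

fit_ols <- function(X, y, params) {
  Xi <- cbind(1, X)
  cf <- qr.coef(qr(Xi), y)
  cf[is.na(cf)] <- 0
  ww_fit(function(Xn) drop(cbind(1, Xn) %*% cf))
}

fit_glmnet_linear <- function(X, y, params, alpha) {
  lam <- params$lambda
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lam,
                        standardize = TRUE)
  ww_fit(function(Xn) drop(predict(fit, Xn, s = lam)),
         info = list(lambda = lam))
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

gamma_scale <- function(X) {
  v <- mean(apply(X, 2, var))
  if (!is.finite(v) || v == 0) v <- 1
  1 / (ncol(X) * v)
}

fit_kernel_ridge <- function(X, y, params) {
  s <- std_fit(X)
  Xs <- std_apply(X, s)
  gamma <- if (is.null(params$gamma)) gamma_scale(Xs) else params$gamma
  K <- rbf_kernel(Xs, Xs, gamma)
  ym <- mean(y)
  a <- solve(K + params$lambda * diag(nrow(K)), y - ym)
  ww_fit(function(Xn) {
    drop(rbf_kernel(std_apply(Xn, s), Xs, gamma) %*% a) + ym
  })
}

fit_sgd <- function(X, y, params) {
  s <- std_fit(X)
  Xs <- std_apply(X, s)
  n <- nrow(Xs); p <- ncol(Xs)
  w <- numeric(p); b <- mean(y)
  lam <- params$lambda
  eta0 <- 0.05
  batch <- min(32L, n)
  for (epoch in seq_len(params$epochs %||% 50)) {
    ord <- sample.int(n)
    eta <- eta0 / (1 + 0.1 * (epoch - 1))
    for (start in seq(1, n, by = batch)) {
      ii <- ord[start:min(start + batch - 1, n)]
      r <- drop(Xs[ii, , drop = FALSE] %*% w) + b - y[ii]
      g <- crossprod(Xs[ii, , drop = FALSE], r) / length(ii)
      w <- w - eta * (drop(g) + lam * w)
      b <- b - eta * mean(r)
    }
  }
  ww_fit(function(Xn) drop(std_apply(Xn, s) %*% w) + b)
}

fit_linear_svr <- function(X, y, params) {
  s <- std_fit(X)
  Xs <- std_apply(X, s)
  p <- ncol(Xs)
  eps <- params$eps %||% 0.1
  C <- params$cost
  h <- 0.01
  obj <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1]
    r <- drop(Xs %*% w) + b - y
    0.5 * sum(w^2) + C * sum(eps_loss(r, eps, h))
  }
  grad <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1]
    r <- drop(Xs %*% w) + b - y
    g <- eps_grad(r, eps, h)
    c(w + C * drop(crossprod(Xs, g)), C * sum(g))
  }
  th <- optim(c(numeric(p), mean(y)), obj, grad, method = "L-BFGS-B",
              control = list(maxit = 300))$par
  ww_fit(function(Xn) drop(std_apply(Xn, s) %*% th[seq_len(p)]) + th[p + 1])
}

fit_svr_rbf <- function(X, y, params) {
  s <- std_fit(X)
  Xs <- std_apply(X, s)
  gamma <- if (is.null(params$gamma)) gamma_scale(Xs) else params$gamma
  K <- rbf_kernel(Xs, Xs, gamma)
  n <- nrow(K)
  eps <- params$eps %||% 0.1
  C <- params$cost
  h <- 0.01
  obj <- function(th) {
    a <- th[seq_len(n)]; b <- th[n + 1]
    f <- drop(K %*% a) + b
    0.5 * sum(a * drop(K %*% a)) + C * sum(eps_loss(f - y, eps, h))
  }
  grad <- function(th) {
    a <- th[seq_len(n)]; b <- th[n + 1]
    Ka <- drop(K %*% a)
    g <- eps_grad(Ka + b - y, eps, h)
    c(Ka + C * drop(K %*% g), C * sum(g))
  }
  th <- optim(c(numeric(n), mean(y)), obj, grad, method = "L-BFGS-B",
              control = list(maxit = 300))$par
  a <- th[seq_len(n)]; b <- th[n + 1]
  ww_fit(function(Xn) {
    drop(rbf_kernel(std_apply(Xn, s), Xs, gamma) %*% a) + b
  })
}

fit_mlp <- function(X, y, params) {
  s <- std_fit(X)
  Xs <- std_apply(X, s)
  n <- nrow(Xs); p <- ncol(Xs)
  hsz <- params$size
  decay <- params$decay
  np <- p * hsz + hsz + hsz + 1
  unpack <- function(th) {
    W1 <- matrix(th[seq_len(p * hsz)], p, hsz)
    b1 <- th[p * hsz + seq_len(hsz)]
    w2 <- th[p * hsz + hsz + seq_len(hsz)]
    b2 <- th[np]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  fwd <- function(Xm, pr) {
    a1 <- tanh(sweep(Xm %*% pr$W1, 2, pr$b1, "+"))
    list(a1 = a1, yhat = drop(a1 %*% pr$w2) + pr$b2)
  }
  obj <- function(th) {
    pr <- unpack(th)
    f <- fwd(Xs, pr)
    mean((f$yhat - y)^2) / 2 +
      decay * (sum(pr$W1^2) + sum(pr$w2^2)) / 2
  }
  grad <- function(th) {
    pr <- unpack(th)
    f <- fwd(Xs, pr)
    d <- (f$yhat - y) / n
    gw2 <- drop(crossprod(f$a1, d)) + decay * pr$w2
    gb2 <- sum(d)
    dz1 <- (d %o% pr$w2) * (1 - f$a1^2)
    gW1 <- crossprod(Xs, dz1) + decay * pr$W1
    gb1 <- colSums(dz1)
    c(as.numeric(gW1), gb1, gw2, gb2)
  }
  th0 <- c(rnorm(np - 1) * 0.1, mean(y))
  th <- optim(th0, obj, grad, method = "L-BFGS-B",
              control = list(maxit = params$maxit %||% 200))$par
  pr <- unpack(th)
  ww_fit(function(Xn) fwd(std_apply(Xn, s), pr)$yhat)
}

fit_knn <- function(X, y, params) {
  k <- params$k
  ww_fit(function(Xn) {
    d2 <- outer(rowSums(Xn^2), rowSums(X^2), "+") - 2 * tcrossprod(Xn, X)
    apply(d2, 1, function(dr) mean(y[order(dr)[seq_len(min(k, length(y)))]]))
  })
}

fit_rf_learner <- function(X, y, params) {
  fo <- fit_forest(X, y,
                   n_trees = params$n_trees %||% 150,
                   mtry = params$mtry,
                   max_depth = params$max_depth %||% Inf,
                   min_split = params$min_split %||% 2)
  ww_fit(function(Xn) predict(fo, Xn), info = list(forest = fo))
}

fit_dt <- function(X, y, params) {
  fo <- fit_forest(X, y, n_trees = 1, mtry = ncol(as_feature_matrix(X)),
                   max_depth = params$max_depth %||% Inf,
                   min_split = params$min_split %||% 2, bootstrap = FALSE)
  ww_fit(function(Xn) predict(fo, Xn), info = list(forest = fo))
}

fit_gbr <- function(X, y, params) {
  Xm <- as_feature_matrix(X)
  n <- nrow(Xm)
  M <- params$n_rounds %||% 100
  lr <- params$learning_rate %||% 0.1
  depth <- params$max_depth %||% 3
  f0 <- mean(y)
  pred <- rep(f0, n)
  trees <- vector("list", M)
  idx <- as.integer(seq_len(n) - 1L)
  for (m in seq_len(M)) {
    tr <- cpp_fit_tree(Xm, y - pred, idx, ncol(Xm), as.integer(depth),
                       2L, 1L, FALSE)
    pred <- pred + lr * cpp_predict_tree(tr, Xm)
    trees[[m]] <- tr
  }
  ww_fit(function(Xn) {
    out <- rep(f0, nrow(Xn))
    for (tr in trees) out <- out + lr * cpp_predict_tree(tr, Xn)
    out
  })
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

fit_adaboost <- function(X, y, params) {
  Xm <- as_feature_matrix(X)
  n <- nrow(Xm)
  M <- params$n_estimators %||% 50
  depth <- params$max_depth %||% 4
  w <- rep(1 / n, n)
  trees <- list()
  betas <- numeric(0)
  for (m in seq_len(M)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    tr <- cpp_fit_tree(Xm, y, as.integer(idx - 1L), ncol(Xm),
                       as.integer(depth), 2L, 1L, FALSE)
    pred <- cpp_predict_tree(tr, Xm)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax == 0) {
      trees <- c(trees, list(tr)); betas <- c(betas, 1e-10)
      break
    }
    err <- err / emax
    ebar <- sum(w * err)
    if (ebar >= 0.5) {
      if (length(trees) == 0) { trees <- list(tr); betas <- 0.999 }
      break
    }
    beta <- ebar / (1 - ebar)
    trees <- c(trees, list(tr))
    betas <- c(betas, beta)
    w <- w * beta^(1 - err)
    w <- w / sum(w)
  }
  lw <- log(1 / betas)
  ww_fit(function(Xn) {
    pm <- vapply(trees, function(tr) cpp_predict_tree(tr, Xn),
                 numeric(nrow(Xn)))
    if (nrow(Xn) == 1L) pm <- matrix(pm, nrow = 1L)
    apply(pm, 1, weighted_median, w = lw)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Registry of regression algorithms
#'
#' Returns the named list of learners available to
#' [nested_cv_benchmark()]. Each entry has a `fit(X, y, params)` function
#' returning an object with a `predict` method, and a `grid` of
#' hyperparameter candidates searched by the inner cross-validation loop.
#' Grids are intentionally compact so the full benchmark stays tractable on
#' one CPU; they can be overridden per learner.
#'
#' @param learners optional character vector to subset the registry.
#' @return named list of learner definitions.
#' @export
regressor_registry <- function(learners = NULL) {
  reg <- list(
    mlr = list(fit = fit_ols, grid = list(list())),
    ridge = list(fit = function(X, y, p) fit_glmnet_linear(X, y, p, 0),
                 grid = lapply(c(0.01, 0.1, 1), function(l)
                   list(lambda = l))),
    kernel_ridge = list(fit = fit_kernel_ridge,
                        grid = lapply(c(0.1, 1), function(l)
                          list(lambda = l))),
    sgd = list(fit = fit_sgd,
               grid = lapply(c(1e-4, 1e-2), function(l)
                 list(lambda = l, epochs = 40))),
    linear_svr = list(fit = fit_linear_svr,
                      grid = lapply(c(0.1, 1), function(co)
                        list(cost = co))),
    rf = list(fit = fit_rf_learner,
              grid = list(list(n_trees = 150))),
    gbr = list(fit = fit_gbr,
               grid = list(list(n_rounds = 100, learning_rate = 0.1,
                                max_depth = 3))),
    adaboost = list(fit = fit_adaboost,
                    grid = list(list(n_estimators = 50, max_depth = 4))),
    dt = list(fit = fit_dt,
              grid = lapply(c(5, 12), function(d) list(max_depth = d))),
    mlp = list(fit = fit_mlp,
               grid = list(list(size = 16, decay = 0.1))),
    svr_rbf = list(fit = fit_svr_rbf,
                   grid = list(list(cost = 1))),
    knn = list(fit = fit_knn,
               grid = lapply(c(1, 3, 5), function(k) list(k = k)))
  )
  if (!is.null(learners)) {
    unknown <- setdiff(learners, names(reg))
    if (length(unknown) > 0) {
      stop("unknown learner(s): ", paste(unknown, collapse = ", "))
    }
    reg <- reg[learners]
  }
  reg
}
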