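# Native implementations of the five classifier types used by the ensemble.
# Training sets are small (2 x |train positives| genes) and features are
# binary, so pure-R learners with vectorized split search are fast enough.

.design_matrix <- function(matrix, genes, features) {
  miss <- setdiff(features, feature_ids(matrix))
  if (length(miss)) stop("missing features: ", paste(head(miss, 5), collapse = ", "))
  as.matrix(.subset_rows(matrix, genes)[, features, drop = FALSE])
}

# ---- ridge-logistic regression (IRLS) --------------------------------------

.fit_lr <- function(X, y, hyper = list(), seed = NULL) {
  lambda <- hyper$lambda %||% 1.0
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)  # intercept unpenalized
  for (it in 1:50) {
    eta <- drop(Xi %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xi * w, Xi) + pen
    beta_new <- drop(solve(H, crossprod(Xi * w, z)))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  structure(list(beta = beta, features = colnames(X)), class = "rmp_lr")
}

.predict_lr <- function(fit, X)
  plogis(drop(cbind(1, X[, fit$features, drop = FALSE]) %*% fit$beta))

# ---- Gaussian naive Bayes ---------------------------------------------------

.fit_gnb <- function(X, y, hyper = list(), seed = NULL) {
  eps_frac <- hyper$var_smoothing %||% 1e-9
  stats_for <- function(cls) {
    Xc <- X[y == cls, , drop = FALSE]
    list(mu = colMeans(Xc),
         var = colMeans(Xc^2) - colMeans(Xc)^2,
         prior = nrow(Xc) / nrow(X))
  }
  s0 <- stats_for(0L); s1 <- stats_for(1L)
  eps <- eps_frac * max(c(s0$var, s1$var, 1e-12))
  s0$var <- s0$var + eps; s1$var <- s1$var + eps
  structure(list(s0 = s0, s1 = s1, features = colnames(X)), class = "rmp_gnb")
}

.predict_gnb <- function(fit, X) {
  X <- X[, fit$features, drop = FALSE]
  loglik <- function(s) {
    const <- -0.5 * sum(log(2 * pi * s$var))
    const - 0.5 * colSums((t(X) - s$mu)^2 / s$var) + log(s$prior)
  }
  l0 <- loglik(fit$s0); l1 <- loglik(fit$s1)
  1 / (1 + exp(pmin(pmax(l0 - l1, -700), 700)))
}

# ---- support vector machine (kernelized Pegasos + Platt scaling) ------------

.kernel_matrix <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(tcrossprod(A, B))
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

.pegasos <- function(K, y, lambda, n_iter) {
  n <- length(y)
  ypm <- 2 * y - 1
  alpha <- numeric(n)
  idx <- sample.int(n, n_iter, replace = TRUE)
  for (t in seq_len(n_iter)) {
    i <- idx[t]
    f <- sum(alpha * ypm * K[, i]) / (lambda * t)
    if (ypm[i] * f < 1) alpha[i] <- alpha[i] + 1
  }
  alpha * ypm / (lambda * n_iter)
}

.fit_svm <- function(X, y, hyper = list(), seed = 1L) {
  kernel <- hyper$kernel %||% "linear"
  cost <- hyper$cost %||% 1
  gamma <- hyper$gamma %||% (1 / ncol(X))
  n_iter <- hyper$n_iter %||% 10000L
  n <- nrow(X)
  lambda <- 1 / (cost * n)
  set.seed(seed)
  # Platt calibration on 3-fold out-of-fold decision values
  folds <- .stratified_folds(y, 3L, seed)
  dec_oof <- numeric(n)
  for (f in folds) {
    tr <- setdiff(seq_len(n), f)
    Ktr <- .kernel_matrix(X[tr, , drop = FALSE], X[tr, , drop = FALSE], kernel, gamma)
    coefs <- .pegasos(Ktr, y[tr], 1 / (cost * length(tr)), n_iter)
    Kte <- .kernel_matrix(X[tr, , drop = FALSE], X[f, , drop = FALSE], kernel, gamma)
    dec_oof[f] <- drop(crossprod(Kte, coefs))
  }
  platt <- suppressWarnings(glm(y ~ d, family = binomial(),
                                data = data.frame(y = y, d = dec_oof)))
  K <- .kernel_matrix(X, X, kernel, gamma)
  coefs <- .pegasos(K, y, lambda, n_iter)
  structure(list(X = X, coefs = coefs, kernel = kernel, gamma = gamma,
                 platt = stats::coef(platt), features = colnames(X)),
            class = "rmp_svm")
}

.predict_svm <- function(fit, X) {
  K <- .kernel_matrix(fit$X, X[, fit$features, drop = FALSE], fit$kernel, fit$gamma)
  d <- drop(crossprod(K, fit$coefs))
  plogis(fit$platt[1L] + fit$platt[2L] * d)
}

# ---- CART on binary features ------------------------------------------------
# A split is just a feature index: x == 0 goes left, x == 1 goes right.

.grow_tree <- function(X, idx, resp, depth, ctl) {
  # resp: list(kind = "gini", y = 0/1) or list(kind = "newton", g, h, lambda)
  node_value <- function(ii) {
    if (resp$kind == "gini") mean(resp$y[ii])
    else -sum(resp$g[ii]) / (sum(resp$h[ii]) + resp$lambda)
  }
  leaf <- function(ii) list(leaf = TRUE, value = node_value(ii), n = length(ii))
  if (depth >= ctl$max_depth || length(idx) < ctl$min_split) return(leaf(idx))
  if (resp$kind == "gini" && length(unique(resp$y[idx])) == 1L) return(leaf(idx))
  p <- ncol(X)
  cand <- if (is.finite(ctl$mtry) && ctl$mtry < p) sample.int(p, ctl$mtry) else seq_len(p)
  Xs <- X[idx, cand, drop = FALSE]
  n1 <- colSums(Xs)
  n0 <- length(idx) - n1
  ok <- n1 >= ctl$min_leaf & n0 >= ctl$min_leaf
  if (!any(ok)) return(leaf(idx))
  if (resp$kind == "gini") {
    y1 <- drop(crossprod(Xs, resp$y[idx]))       # positives going right
    y0 <- sum(resp$y[idx]) - y1
    gini_side <- function(pos, n) ifelse(n > 0, 2 * (pos / n) * (1 - pos / n), 0)
    score <- (n0 * gini_side(y0, n0) + n1 * gini_side(y1, n1)) / length(idx)
    parent <- gini_side(sum(resp$y[idx]), length(idx))
    gain <- ifelse(ok, parent - score, -Inf)
  } else {
    G1 <- drop(crossprod(Xs, resp$g[idx])); G0 <- sum(resp$g[idx]) - G1
    H1 <- drop(crossprod(Xs, resp$h[idx])); H0 <- sum(resp$h[idx]) - H1
    lam <- resp$lambda
    gain_raw <- 0.5 * (G0^2 / (H0 + lam) + G1^2 / (H1 + lam) -
                       (G0 + G1)^2 / (H0 + H1 + lam))
    gain <- ifelse(ok, gain_raw, -Inf)
  }
  best <- which.max(gain)
  if (!is.finite(gain[best]) || gain[best] <= 1e-12) return(leaf(idx))
  j <- cand[best]
  go_right <- X[idx, j] == 1
  list(leaf = FALSE, feature = j, gain = gain[best], n = length(idx),
       left = .grow_tree(X, idx[!go_right], resp, depth + 1L, ctl),
       right = .grow_tree(X, idx[go_right], resp, depth + 1L, ctl))
}

.tree_predict <- function(node, X) {
  out <- numeric(nrow(X))
  rec <- function(nd, ii) {
    if (!length(ii)) return()
    if (nd$leaf) { out[ii] <<- nd$value; return() }
    right <- X[ii, nd$feature] == 1
    rec(nd$left, ii[!right]); rec(nd$right, ii[right])
  }
  rec(node, seq_len(nrow(X)))
  out
}

.tree_gains <- function(node, acc = numeric(0)) {
  if (node$leaf) return(acc)
  ch <- as.character(node$feature)
  prev <- if (ch %in% names(acc)) acc[[ch]] else 0
  acc[ch] <- prev + node$gain * node$n
  acc <- .tree_gains(node$left, acc)
  .tree_gains(node$right, acc)
}

# ---- random forest ----------------------------------------------------------

.fit_rf <- function(X, y, hyper = list(), seed = 1L) {
  n_trees <- hyper$n_trees %||% 100L
  ctl <- list(mtry = hyper$mtry %||% max(1L, floor(sqrt(ncol(X)))),
              max_depth = hyper$max_depth %||% 12L,
              min_split = hyper$min_split %||% 2L,
              min_leaf = hyper$min_leaf %||% 1L)
  set.seed(seed)
  trees <- vector("list", n_trees)
  gains <- numeric(ncol(X))
  for (b in seq_len(n_trees)) {
    boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
    trees[[b]] <- .grow_tree(X, boot, list(kind = "gini", y = y), 0L, ctl)
    g <- .tree_gains(trees[[b]])
    if (length(g)) gains[as.integer(names(g))] <- gains[as.integer(names(g))] + g
  }
  imp <- if (sum(gains) > 0) gains / sum(gains) else gains
  structure(list(trees = trees, features = colnames(X),
                 importances = setNames(imp, colnames(X))),
            class = "rmp_rf")
}

.predict_rf <- function(fit, X) {
  X <- X[, fit$features, drop = FALSE]
  rowMeans(vapply(fit$trees, function(tr) .tree_predict(tr, X),
                  numeric(nrow(X))))
}

# ---- gradient boosting (second-order, logistic loss) ------------------------

.fit_gb <- function(X, y, hyper = list(), seed = 1L) {
  n_trees <- hyper$n_trees %||% 100L
  lr <- hyper$learning_rate %||% 0.1
  reg_lambda <- hyper$reg_lambda %||% 1.0
  ctl <- list(mtry = Inf,
              max_depth = hyper$max_depth %||% 3L,
              min_split = hyper$min_split %||% 2L,
              min_leaf = hyper$min_leaf %||% 1L)
  set.seed(seed)
  n <- nrow(X)
  base <- mean(y)
  F0 <- log(pmax(base, 1e-6) / pmax(1 - base, 1e-6))
  Fv <- rep(F0, n)
  trees <- vector("list", n_trees)
  gains <- numeric(ncol(X))
  for (b in seq_len(n_trees)) {
    p <- plogis(Fv)
    resp <- list(kind = "newton", g = p - y, h = pmax(p * (1 - p), 1e-12),
                 lambda = reg_lambda)
    tr <- .grow_tree(X, seq_len(n), resp, 0L, ctl)
    trees[[b]] <- tr
    Fv <- Fv + lr * .tree_predict(tr, X)
    g <- .tree_gains(tr)
    if (length(g)) gains[as.integer(names(g))] <- gains[as.integer(names(g))] + g
  }
  imp <- if (sum(gains) > 0) gains / sum(gains) else gains
  structure(list(trees = trees, F0 = F0, lr = lr, features = colnames(X),
                 importances = setNames(imp, colnames(X))),
            class = "rmp_gb")
}

.predict_gb <- function(fit, X) {
  X <- X[, fit$features, drop = FALSE]
  Fv <- rep(fit$F0, nrow(X))
  for (tr in fit$trees) Fv <- Fv + fit$lr * .tree_predict(tr, X)
  plogis(Fv)
}

# ---- common dispatch --------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

.fit_model <- function(model_type, X, y, hyper = list(), seed = 1L) {
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  switch(model_type,
         LR  = .fit_lr(X, y, hyper, seed),
         GNB = .fit_gnb(X, y, hyper, seed),
         SVM = .fit_svm(X, y, hyper, seed),
         RF  = .fit_rf(X, y, hyper, seed),
         GB  = .fit_gb(X, y, hyper, seed),
         stop("unknown model type: ", model_type))
}

.predict_model <- function(fit, X) {
  p <- switch(class(fit),
              rmp_lr = .predict_lr(fit, X),
              rmp_gnb = .predict_gnb(fit, X),
              rmp_svm = .predict_svm(fit, X),
              rmp_rf = .predict_rf(fit, X),
              rmp_gb = .predict_gb(fit, X),
              stop("unknown fit class"))
  pmin(pmax(p, 0), 1)
}

.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cls in unique(y)) {
    ii <- sample(which(y == cls))
    fold_of[ii] <- rep_len(seq_len(k), length(ii))
  }
  split(seq_along(y), fold_of)
}
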