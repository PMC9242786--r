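# The five regression learners behind COP-path prediction. Each fitter
# takes a standardized feature matrix and the raw target (mm) and returns a
# list with a `predict_fn(newx)` plus a `converged` flag.

fit_lsboost <- function(x, y, hyper, seed) {
  booster <- xgboost::xgboost(
    x = x, y = y,
    objective = "reg:squarederror",
    nrounds = hyper$n_learners,
    learning_rate = hyper$learning_rate,
    max_depth = hyper$max_depth,
    nthreads = 1, seed = seed, verbosity = 0)
  list(predict_fn = function(newx) predict(booster, newx), converged = TRUE)
}

fit_bagging <- function(x, y, hyper, seed) {
  rf <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = hyper$n_learners, mtry = ncol(x),
    nodesize = hyper$nodesize, replace = TRUE))
  list(predict_fn = function(newx) unname(predict(rf, newx)),
       converged = TRUE)
}

# Robust sd via the interquartile range; 1.349 is the IQR of a standard
# normal, so IQR/1.349 estimates sd without tail sensitivity.
robust_sd_iqr <- function(y) {
  unname(diff(quantile(y, c(0.25, 0.75), type = 7))) / 1.349
}

fit_svm <- function(x, y, hyper, seed) {
  # target standardized with training stats so the default cost is on a
  # sensible scale; epsilon = one tenth of the IQR-based robust sd of the
  # (scaled) training targets
  mu <- mean(y)
  s <- sd(y)
  if (s == 0) {
    # degenerate constant target: nothing to learn
    return(list(predict_fn = function(newx) rep(mu, nrow(newx)),
                converged = TRUE))
  }
  ys <- (y - mu) / s
  eps <- robust_sd_iqr(ys) / 10
  fit <- e1071::svm(x = x, y = ys, type = "eps-regression",
                    kernel = "radial", cost = hyper$cost,
                    epsilon = eps, scale = FALSE)
  list(predict_fn = function(newx) unname(predict(fit, newx)) * s + mu,
       converged = TRUE)
}

# --- two-hidden-layer feedforward network (tanh, linear output) ----------

mlp_unpack <- function(w, d, h1, h2) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(d * h1)], d, h1); i <- i + d * h1
  b1 <- w[i + seq_len(h1)]; i <- i + h1
  W2 <- matrix(w[i + seq_len(h1 * h2)], h1, h2); i <- i + h1 * h2
  b2 <- w[i + seq_len(h2)]; i <- i + h2
  W3 <- w[i + seq_len(h2)]; i <- i + h2
  b3 <- w[i + 1L]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
}

mlp_forward <- function(p, x) {
  a1 <- tanh(sweep(x %*% p$W1, 2, p$b1, "+"))
  a2 <- tanh(sweep(a1 %*% p$W2, 2, p$b2, "+"))
  drop(a2 %*% p$W3) + p$b3
}

fit_ann <- function(x, y, hyper, seed) {
  d <- ncol(x)
  h1 <- hyper$nodes[1L]
  h2 <- hyper$nodes[2L]
  npar <- d * h1 + h1 + h1 * h2 + h2 + h2 + 1L
  mu <- mean(y)
  s <- sd(y)
  if (s == 0) s <- 1
  ys <- (y - mu) / s
  loss <- function(w) {
    p <- mlp_unpack(w, d, h1, h2)
    mean((mlp_forward(p, x) - ys)^2)
  }
  w0 <- with_seed(seed, rnorm(npar, sd = 0.5))
  opt <- optim(w0, loss, method = "BFGS",
               control = list(maxit = hyper$maxit, reltol = 1e-10))
  p <- mlp_unpack(opt$par, d, h1, h2)
  list(predict_fn = function(newx) mlp_forward(p, newx) * s + mu,
       converged = opt$convergence == 0L)
}

# --- Gaussian process regression, squared-exponential kernel -------------

gp_kernel <- function(d2, sigma_f, ell) {
  sigma_f^2 * exp(-0.5 * d2 / ell^2)
}

sq_dists <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# Negative log marginal likelihood with the constant-mean coefficient
# profiled out by generalized least squares.
gp_nll <- function(logpar, d2, y) {
  sigma_f <- exp(logpar[1L])
  ell <- exp(logpar[2L])
  sigma_n <- exp(logpar[3L])
  n <- length(y)
  K <- gp_kernel(d2, sigma_f, ell) + diag(sigma_n^2 + 1e-8, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  beta <- sum(alpha1 * y) / sum(alpha1)
  r <- y - beta
  ar <- backsolve(ch, forwardsolve(t(ch), r))
  0.5 * sum(r * ar) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
}

fit_gp <- function(x, y, hyper, seed) {
  d2 <- sq_dists(x, x)
  n <- length(y)
  # amplitude initialized to sd(y)/2; length-scale to the median pairwise
  # feature distance; noise to sd(y)/2
  s_y <- sd(y)
  if (s_y == 0) s_y <- 1
  ell0 <- median(sqrt(d2[upper.tri(d2)]))
  if (!is.finite(ell0) || ell0 <= 0) ell0 <- 1
  start <- log(pmax(c(hyper$sigma_f_init(y), ell0, s_y / 2), 1e-6))
  opt <- optim(start, gp_nll, d2 = d2, y = y, method = "BFGS",
               control = list(maxit = 200))
  sigma_f <- exp(opt$par[1L])
  ell <- exp(opt$par[2L])
  sigma_n <- exp(opt$par[3L])
  K <- gp_kernel(d2, sigma_f, ell) + diag(sigma_n^2 + 1e-8, n)
  ch <- chol(K)
  alpha1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  beta <- sum(alpha1 * y) / sum(alpha1)
  alpha <- backsolve(ch, forwardsolve(t(ch), y - beta))
  list(predict_fn = function(newx) {
    ks <- gp_kernel(sq_dists(newx, x), sigma_f, ell)
    drop(ks %*% alpha) + beta
  }, converged = opt$convergence == 0L)
}

learner_registry <- list(lsboost = fit_lsboost, bagging = fit_bagging,
                         svm = fit_svm, ann = fit_ann, gp = fit_gp)

default_hyper <- function(algorithm) {
  switch(algorithm,
    lsboost = list(n_learners = 100, learning_rate = 0.1, max_depth = 3),
    bagging = list(n_learners = 100, nodesize = 5),
    svm = list(cost = 1),
    ann = list(nodes = c(3L, 4L), maxit = 1000),
    gp = list(sigma_f_init = function(y) sd(y) / 2),
    stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE))
}
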