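## Gaussian-process machinery for the surrogate-based optimiser: ARD
## squared-exponential regression with type-II maximum likelihood, and
## binary classification via the Laplace approximation.

ard_kernel <- function(X1, X2, ls, sf2) {
  d2 <- matrix(0, nrow(X1), nrow(X2))
  for (k in seq_len(ncol(X1)))
    d2 <- d2 + outer(X1[, k] / ls[k], X2[, k] / ls[k], `-`)^2
  sf2 * exp(-0.5 * d2)
}

scale01 <- function(X, lo, hi) sweep(sweep(X, 2, lo), 2, pmax(hi - lo, 1e-12), `/`)

#' Fit a Gaussian-process regression surrogate
#'
#' Anisotropic squared-exponential kernel with constant mean.  Inputs are
#' min-max scaled to the unit cube, outputs standardised.  The kernel
#' hyperparameters (per-dimension lengthscales, signal variance, noise
#' variance) are fitted by maximising the log marginal likelihood with a
#' conjugate-gradient optimiser; the returned hyperparameters never have
#' lower marginal likelihood than the initial ones.
#'
#' @param X Input matrix (n x d).
#' @param y Output vector (length n).
#' @param bounds Optional d x 2 matrix of input bounds for scaling
#'   (defaults to the data range).
#' @param noise_var Fixed noise variance on the standardised scale, or
#'   `NULL` to fit it.
#' @param maxit Optimiser iterations.
#' @return An object of class `gp_fit`.
#' @export
gp_fit <- function(X, y, bounds = NULL, noise_var = NULL, maxit = 60) {
  X <- as.matrix(X); n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("at least 2 training points are required")
  if (is.null(bounds)) bounds <- cbind(apply(X, 2, min), apply(X, 2, max))
  Xs <- scale01(X, bounds[, 1], bounds[, 2])
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1    # constant outputs
  ys <- (y - mu) / sdy
  fit_noise <- is.null(noise_var)
  nlml <- function(h) {
    ls <- exp(h[1:d]); sf2 <- exp(2 * h[d + 1])
    sn2 <- if (fit_noise) exp(2 * h[d + 2]) else noise_var
    K <- ard_kernel(Xs, Xs, ls, sf2) + diag(sn2 + 1e-10, n)
    ch <- try(chol(K), silent = TRUE)
    if (inherits(ch, "try-error")) {
      ch <- try(chol(K + diag(1e-6, n)), silent = TRUE)  # jitter
      if (inherits(ch, "try-error")) return(1e10)
    }
    a <- backsolve(ch, forwardsolve(t(ch), ys))
    0.5 * sum(ys * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }
  h0 <- c(rep(log(0.3), d), log(1), if (fit_noise) log(0.05))
  opt <- try(stats::optim(h0, nlml, method = "CG",
                          control = list(maxit = maxit)), silent = TRUE)
  h <- if (!inherits(opt, "try-error") && opt$value <= nlml(h0)) opt$par else h0
  ls <- exp(h[1:d]); sf2 <- exp(2 * h[d + 1])
  sn2 <- if (fit_noise) exp(2 * h[d + 2]) else noise_var
  K <- ard_kernel(Xs, Xs, ls, sf2) + diag(sn2 + 1e-10, n)
  ch <- chol(K + diag(1e-9, n))
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  structure(list(Xs = Xs, bounds = bounds, mu = mu, sdy = sdy,
                 ls = ls, sf2 = sf2, sn2 = sn2, chol = ch, alpha = alpha,
                 nlml = nlml(h)),
            class = "gp_fit")
}

#' Predict from a Gaussian-process surrogate
#'
#' @param fit A [gp_fit()].
#' @param Xnew Input matrix (m x d) on the original scale.
#' @param include_noise Add the fitted noise variance to the predictive
#'   variance.
#' @return List with `mean`, `sd` on the original output scale.
#' @export
gp_predict <- function(fit, Xnew, include_noise = FALSE) {
  Xn <- scale01(as.matrix(Xnew), fit$bounds[, 1], fit$bounds[, 2])
  Ks <- ard_kernel(Xn, fit$Xs, fit$ls, fit$sf2)
  mean_s <- drop(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(Ks))
  var_s <- pmax(fit$sf2 - colSums(v^2), 0)
  if (include_noise) var_s <- var_s + fit$sn2
  list(mean = fit$mu + fit$sdy * mean_s,
       sd = fit$sdy * sqrt(var_s))
}

#' Fit a binary Gaussian-process classifier (Laplace approximation)
#'
#' Logistic-link GP classification over +/-1 labels with an anisotropic
#' squared-exponential kernel, used to learn the feasible region of the
#' design space.  Single-class training data yield a constant classifier
#' at that class.
#'
#' @param X Input matrix (n x d).
#' @param label Vector of +1 / -1 labels.
#' @param bounds Optional input bounds for scaling.
#' @param ls Lengthscale (scalar or per dimension) on the unit cube.
#' @param sf2 Signal variance.
#' @param maxit Newton iterations for the posterior mode.
#' @return An object of class `gpc_fit`.
#' @export
gpc_fit <- function(X, label, bounds = NULL, ls = 0.3, sf2 = 9,
                    maxit = 50) {
  X <- as.matrix(X); n <- nrow(X); d <- ncol(X)
  if (!all(label %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (is.null(bounds)) bounds <- cbind(apply(X, 2, min), apply(X, 2, max))
  if (length(unique(label)) == 1) {
    return(structure(list(constant = (unique(label) + 1) / 2,
                          bounds = bounds), class = "gpc_fit"))
  }
  Xs <- scale01(X, bounds[, 1], bounds[, 2])
  ls <- rep(ls, length.out = d)
  K <- ard_kernel(Xs, Xs, ls, sf2) + diag(1e-8, n)
  f <- numeric(n)
  for (it in seq_len(maxit)) {     # Newton iterations for the mode
    pi_ <- stats::plogis(f)
    t_ <- (label + 1) / 2
    W <- pi_ * (1 - pi_)
    sW <- sqrt(pmax(W, 1e-12))
    B <- diag(n) + (sW %o% sW) * K
    L <- chol(B)
    b <- W * f + (t_ - pi_)
    a <- b - sW * backsolve(L, forwardsolve(t(L), sW * (K %*% b)))
    f_new <- drop(K %*% a)
    if (max(abs(f_new - f)) < 1e-8) { f <- f_new; break }
    f <- f_new
  }
  pi_ <- stats::plogis(f)
  grad <- (label + 1) / 2 - pi_
  W <- pi_ * (1 - pi_)
  sW <- sqrt(pmax(W, 1e-12))
  L <- chol(diag(n) + (sW %o% sW) * K)
  structure(list(Xs = Xs, bounds = bounds, ls = ls, sf2 = sf2,
                 grad = grad, sW = sW, L = L, constant = NULL),
            class = "gpc_fit")
}

#' Probability of feasibility
#'
#' @param fit A [gpc_fit()].
#' @param Xnew Input matrix on the original scale.
#' @return Vector of P(feasible | x) in `[0, 1]`.
#' @export
gpc_predict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (!is.null(fit$constant)) return(rep(fit$constant, nrow(Xnew)))
  Xn <- scale01(Xnew, fit$bounds[, 1], fit$bounds[, 2])
  Ks <- ard_kernel(Xn, fit$Xs, fit$ls, fit$sf2)
  fbar <- drop(Ks %*% fit$grad)
  v <- forwardsolve(t(fit$L), fit$sW * t(Ks))
  var_f <- pmax(fit$sf2 - colSums(v^2), 0)
  ## MacKay's probit-style correction of the logistic link
  stats::plogis(fbar / sqrt(1 + pi * var_f / 8))
}
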