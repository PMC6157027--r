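# ---- internal profiled-likelihood machinery -------------------------------
#
# Model: y = X b + sum_k u_k + e,  Var(y) = sigma2 * V(theta),
#        V(theta) = sum_k theta_k K_k + (1 - sum theta_k) I.
# For a single combined kernel K with eigendecomposition K = U D U', rotating
# by U' makes V diagonal: w_i = s d_i + (1 - s). b is then profiled by GLS and
# sigma2 in closed form, leaving a 1-D concave-ish problem in s solved by a
# deterministic grid + golden-section refinement; boundary s = 0 is evaluated
# exactly. Two structured kernels are handled by profiling additionally over
# the mixing ratio p with K_p = p K_1 + (1 - p) K_2 and theta = s (p, 1 - p);
# p = 1 reproduces the single-kernel (null) computation bit-for-bit, which
# guarantees ll_full >= ll_null.

.vcRotate <- function(y, X, K) {
  dimnames(K) <- NULL
  ed <- eigSym(K)
  list(d = drop(ed$values), yt = drop(crossprod(ed$vectors, y)),
       Xt = crossprod(ed$vectors, X))
}

# profiled log-likelihood at genetic fraction s; returns -Inf when V ~ singular
.vcProfile <- function(s, d, yt, Xt, reml = FALSE) {
  w <- s * d + (1 - s)
  if (min(w) < 1e-12) return(list(ll = -Inf))
  sw <- sqrt(w)
  Xw <- Xt / sw
  yw <- yt / sw
  fit <- lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  n <- length(yt)
  if (!reml) {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + sum(log(w)) + n * log(s2) + n)
  } else {
    q <- ncol(Xt)
    s2 <- rss / (n - q)
    ldx <- as.numeric(determinant(crossprod(Xw), logarithm = TRUE)$modulus)
    ll <- -0.5 * ((n - q) * log(2 * pi) + sum(log(w)) + ldx +
                  (n - q) * log(s2) + (n - q))
  }
  list(ll = ll, beta = fit$coefficients, sigma2 = s2)
}

# maximize over s in [0, 1]; deterministic; exact boundary at s = 0
.vcFit1 <- function(d, yt, Xt, reml = FALSE, snapTol = 1e-6) {
  f <- function(s) .vcProfile(s, d, yt, Xt, reml)$ll
  grid <- c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 1 - 1e-7)
  vals <- vapply(grid, f, 0)
  nEval <- length(grid)
  b <- which.max(vals)
  lo <- grid[max(1L, b - 1L)]
  hi <- grid[min(length(grid), b + 1L)]
  op <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  nEval <- nEval + 40L
  s <- op$maximum
  ll <- op$objective
  if (vals[b] >= ll) { s <- grid[b]; ll <- vals[b] }
  if (s < snapTol && vals[1L] >= ll - 1e-9) { s <- 0; ll <- vals[1L] }
  prof <- .vcProfile(s, d, yt, Xt, reml)
  list(s = s, ll = prof$ll, beta = prof$beta, sigma2 = prof$sigma2,
       nEval = nEval)
}

.asKernelList <- function(kernels) {
  if (is(kernels, "MethylKernel")) kernels <- list(kernelMatrix(kernels))
  if (is.matrix(kernels)) kernels <- list(kernels)
  kernels <- lapply(kernels, function(k)
    if (is(k, "MethylKernel")) kernelMatrix(k) else k)
  if (is.null(names(kernels)) || any(!nzchar(names(kernels))))
    names(kernels) <- paste0("h", seq_along(kernels), "2")
  kernels
}

.designMatrix <- function(n, covariates) {
  if (is.null(covariates)) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    X <- cbind(`(Intercept)` = 1, covariates)
  }
  if (qr(X)$rank < ncol(X))
    stop("covariate design matrix is rank deficient")
  X
}

#' Exact multivariate-normal log-likelihood of a variance-component model
#'
#' Evaluates the log-density of the residual `trait - X %*% betas` under
#' covariance \eqn{\sigma^2 (\sum_k \theta_k K_k + e^2 I)} with
#' \eqn{e^2 = 1 - \sum_k \theta_k}, via a Cholesky factorization. If the
#' covariance is numerically singular a ridge (default `1e-8` on the
#' diagonal) is applied once, with a warning.
#'
#' @param trait numeric response vector.
#' @param covariates optional matrix/data.frame of fixed-effect covariates
#'   (an intercept is always prepended).
#' @param kernels list of symmetric PSD matrices (or [MethylKernel-class]
#'   objects), all aligned to `trait`.
#' @param fractions numeric vector of variance fractions, one per kernel;
#'   each in \[0, 1\] with sum at most 1.
#' @param sigma2 total variance (positive).
#' @param betas fixed-effect values, length `ncol(X)` (intercept first).
#' @param ridge diagonal jitter used on factorization failure.
#' @return the log-likelihood (a single number).
#' @export
vcLogLik <- function(trait, covariates = NULL, kernels, fractions, sigma2,
                     betas, ridge = 1e-8) {
  kernels <- .asKernelList(kernels)
  stopifnot(length(fractions) == length(kernels), sigma2 > 0,
            all(fractions >= 0), sum(fractions) <= 1 + 1e-12)
  n <- length(trait)
  X <- .designMatrix(n, covariates)
  stopifnot(length(betas) == ncol(X))
  r <- trait - drop(X %*% betas)
  V <- diag(1 - sum(fractions), n)
  for (k in seq_along(kernels)) V <- V + fractions[k] * kernels[[k]]
  Om <- sigma2 * V
  ch <- tryCatch(chol(Om), error = function(e) NULL)
  if (is.null(ch)) {
    warning("covariance numerically singular; adding ridge ", ridge)
    ch <- chol(Om + diag(ridge, n))
  }
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

#' Maximum-likelihood fit of the variance-component mixed model
#'
#' Fits \eqn{\Omega = \sigma^2_{Total}(\sum_k h_k^2 K_k + e^2 I)} with fixed
#' effects profiled by GLS and \eqn{\sigma^2_{Total}} profiled in closed form.
#' One structured kernel is fitted by exact 1-D search over its fraction;
#' two kernels are fitted by additionally profiling over the kernel mixing
#' ratio (see the package vignette). Boundary solutions (a fraction exactly
#' 0) are reachable exactly; fractions below `snapTol` are snapped to 0.
#'
#' @param trait numeric response (n >= 10).
#' @param covariates optional fixed-effect covariates (intercept added).
#' @param kernels named list of 1 or 2 symmetric PSD kernel matrices (or
#'   [MethylKernel-class] objects), aligned to `trait`; e.g.
#'   `list(h_r2 = A)` or `list(h_r2 = A, h_meth2 = K)`.
#' @param method `"ML"` (default) or `"REML"`.
#' @param snapTol fractions below this are reported as exactly 0.
#' @param pTol interval tolerance of the mixing-ratio refinement.
#' @return a [VarCompFit-class].
#' @examples
#' ped <- simulatePedigree(nFamilies = 20, seed = 1)
#' A <- additiveMatrix(kinshipMatrix(ped))
#' y <- drop(t(chol(0.5 * A + 0.5 * diag(nrow(A)))) %*% rnorm(nrow(A)))
#' fitVarComp(y, kernels = list(h_r2 = A))
#' @export
fitVarComp <- function(trait, covariates = NULL, kernels, method = "ML",
                       snapTol = 1e-6, pTol = 1e-3) {
  method <- match.arg(method, c("ML", "REML"))
  reml <- method == "REML"
  kernels <- .asKernelList(kernels)
  if (!length(kernels) %in% 1:2)
    stop("fitVarComp supports 1 or 2 structured kernels")
  n <- length(trait)
  if (n < 10L) stop("at least 10 samples are required")
  X <- .designMatrix(n, covariates)
  if (length(kernels) == 1L) {
    rot <- .vcRotate(trait, X, kernels[[1L]])
    ft <- .vcFit1(rot$d, rot$yt, rot$Xt, reml)
    th <- ft$s
    names(th) <- names(kernels)
    return(new("VarCompFit", sigma2 = ft$sigma2, fractions = th,
               e2 = 1 - sum(th), betas = setNames(ft$beta, colnames(X)),
               loglik = ft$ll, converged = is.finite(ft$ll),
               nEvals = ft$nEval, method = method))
  }
  K1 <- kernels[[1L]]
  K2 <- kernels[[2L]]
  cache <- new.env(parent = emptyenv())
  nEval <- 0L
  evalP <- function(p) {
    key <- sprintf("%.12f", p)
    if (!is.null(cache[[key]])) return(cache[[key]])
    Kp <- if (p == 1) K1 else if (p == 0) K2 else p * K1 + (1 - p) * K2
    rot <- .vcRotate(trait, X, Kp)
    ft <- .vcFit1(rot$d, rot$yt, rot$Xt, reml)
    ft$p <- p
    nEval <<- nEval + 1L
    cache[[key]] <- ft
    ft
  }
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  fits <- lapply(grid, evalP)
  lls <- vapply(fits, `[[`, 0, "ll")
  b <- which.max(lls)
  best <- fits[[b]]
  lo <- grid[max(1L, b - 1L)]
  hi <- grid[min(length(grid), b + 1L)]
  if (hi > lo) {
    op <- optimize(function(p) evalP(p)$ll, c(lo, hi), maximum = TRUE,
                   tol = pTol)
    cand <- evalP(op$maximum)
    if (cand$ll > best$ll) best <- cand
  }
  th <- c(best$s * best$p, best$s * (1 - best$p))
  th[th < snapTol] <- 0
  names(th) <- names(kernels)
  new("VarCompFit", sigma2 = best$sigma2, fractions = th, e2 = 1 - sum(th),
      betas = setNames(best$beta, colnames(X)), loglik = best$ll,
      converged = is.finite(best$ll), nEvals = nEval, method = method)
}

#' Fit the polygenic null model and the methylation-augmented full model
#'
#' The null model carries only the additive relationship matrix
#' (\eqn{\Omega = \sigma^2(2\Phi h_r^2 + I e^2)}); the full model adds the
#' gene-specific methylation kernel. Both are fitted by ML with the same
#' deterministic search, and the full-model search includes the null model as
#' a candidate (mixing ratio 1), so `fitLogLik(full) >= fitLogLik(null)`
#' always holds.
#'
#' @param trait numeric response.
#' @param covariates optional fixed-effect covariates.
#' @param phi2 additive relationship matrix \eqn{2\Phi}, aligned to `trait`.
#' @param kernel a [MethylKernel-class] or matrix, aligned to `trait`.
#' @param ... passed to [fitVarComp()].
#' @return list with elements `null` and `full` ([VarCompFit-class]).
#' @export
fitNullAndFull <- function(trait, covariates = NULL, phi2, kernel, ...) {
  E <- if (is(kernel, "MethylKernel")) kernelMatrix(kernel) else kernel
  null <- fitVarComp(trait, covariates, list(h_r2 = phi2), ...)
  full <- fitVarComp(trait, covariates, list(h_r2 = phi2, h_meth2 = E), ...)
  if (full@loglik < null@loglik - 1e-6)
    stop("nesting violation: full-model log-likelihood below null's")
  list(null = null, full = full)
}

#' @rdname varFractions
setMethod("varFractions", "VarCompFit",
          function(x) c(x@fractions, e2 = x@e2))

#' @rdname fitLogLik
setMethod("fitLogLik", "VarCompFit", function(x) x@loglik)

#' Total-variance estimate of a fit
#' @param x a `VarCompFit`.
#' @return numeric \eqn{\hat\sigma^2_{Total}}.
#' @export
sigma2Total <- function(x) x@sigma2

#' Fixed-effect estimates of a fit
#' @param x a `VarCompFit`.
#' @return named numeric vector.
#' @export
fixedEffects <- function(x) x@betas

setMethod("show", "VarCompFit", function(object) {
  fr <- c(object@fractions, e2 = object@e2)
  cat("VarCompFit (", object@method, "): logLik ",
      format(object@loglik, digits = 8), "\n  sigma2 ",
      signif(object@sigma2, 5), "; fractions: ",
      paste(names(fr), signif(fr, 4), sep = "=", collapse = ", "), "\n",
      sep = "")
})
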