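#' Point-normal mixture parameters for SNP effect sizes
#'
#' The model places a point mass at zero on null SNPs and one (`M2`) or two
#' (`M3`) zero-mean normal components on susceptibility SNPs (sSNPs).
#' Effects are on the standardized scale (approximately the SNP-phenotype
#' correlation), so a SNP with true effect `beta` and study size `n`
#' contributes a z-score with variance `intercept_a + n * sigma2` under its
#' component. `intercept_a` is the variance of null-SNP z-scores; values
#' above 1 absorb uncorrected stratification inflation.
#'
#' @param kind `"M2"` (single sSNP component) or `"M3"` (two components).
#' @param pi_c Proportion of reference SNPs that are sSNPs, in `[0, 1)`
#'   (0 is the pure-null model).
#' @param sigma2 M2 effect-size variance (standardized scale).
#' @param sigma2_1,sigma2_2 M3 component variances, `sigma2_1 >= sigma2_2`.
#' @param prop Fraction of sSNPs in the larger-variance component.
#' @param intercept_a Null z-score variance (default 1 = no inflation).
#' @return A list of class `mixture_params`.
#' @export
mixture_params <- function(kind = c("M2", "M3"), pi_c,
                           sigma2 = NULL, sigma2_1 = NULL, sigma2_2 = NULL,
                           prop = NULL, intercept_a = 1) {
  kind <- match.arg(kind)
  stopifnot(is_fraction(pi_c, open_lo = FALSE), intercept_a > 0)
  if (kind == "M2") {
    stopifnot(!is.null(sigma2), sigma2 >= 0)
    sigma2_1 <- sigma2_2 <- prop <- NULL
  } else {
    stopifnot(!is.null(sigma2_1), !is.null(sigma2_2), !is.null(prop),
              sigma2_1 >= 0, sigma2_2 >= 0,
              is_fraction(prop, open_lo = FALSE, open_hi = FALSE))
    if (sigma2_1 < sigma2_2)
      stop("sigma2_1 must be >= sigma2_2 (swap components)")
    sigma2 <- NULL
  }
  structure(list(kind = kind, pi_c = pi_c, sigma2 = sigma2,
                 sigma2_1 = sigma2_1, sigma2_2 = sigma2_2, prop = prop,
                 intercept_a = intercept_a),
            class = "mixture_params")
}

# component weights and per-SNP variances; rows of `v` follow `w`
component_variances <- function(params, n_eff) {
  a <- params$intercept_a
  if (params$kind == "M2") {
    w <- c(1 - params$pi_c, params$pi_c)
    v <- rbind(rep(a, length(n_eff)), a + n_eff * params$sigma2)
  } else {
    w <- c(1 - params$pi_c,
           params$pi_c * params$prop,
           params$pi_c * (1 - params$prop))
    v <- rbind(rep(a, length(n_eff)),
               a + n_eff * params$sigma2_1,
               a + n_eff * params$sigma2_2)
  }
  list(w = w, v = v)
}

#' Marginal density of a z-score under the mixture model
#'
#' For a SNP with effective sample size `n_eff`, the marginal law of the
#' z-score is a mixture of zero-mean normals: the null component with
#' variance `intercept_a` and each sSNP component with variance
#' `intercept_a + n_eff * sigma2_k`.
#'
#' @param z Numeric vector of z-scores.
#' @param n_eff Effective sample sizes (scalar or same length as `z`).
#' @param params A [mixture_params()].
#' @param log Return the log-density?
#' @return Nonnegative density values (or log-densities).
#' @export
marginal_density <- function(z, n_eff, params, log = FALSE) {
  stopifnot(inherits(params, "mixture_params"))
  cv <- component_variances(params, rep_len(n_eff, length(z)))
  if (any(cv$v <= 0)) stop("nonpositive component variance")
  d <- 0
  for (k in seq_along(cv$w))
    d <- d + cv$w[k] * dnorm(z, 0, sqrt(cv$v[k, ]))
  if (log) base::log(d) else d
}

#' Log-likelihood of a summary-statistics table under the mixture model
#'
#' Sum of log marginal densities over SNPs, treating SNPs as effectively
#' LD-independent (the table is expected to be pruned/QC-filtered).
#'
#' @param table Canonical summary-statistics tibble with `z` and `n_eff`.
#' @param params A [mixture_params()].
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(table, params) {
  if (!nrow(table)) stop("empty summary-statistics table")
  sum(marginal_density(table$z, table$n_eff, params, log = TRUE))
}

# ---- internal parameter transforms for bounded maximization -----------------
# theta layout (free scale): M2 (qlogis(pi/.5), log s2 [, a])
#                            M3 (qlogis(pi/.5), log s1, log s2, qlogis(prop) [, a])
PI_MAX <- 0.5
A_BOUNDS <- c(0.8, 1.5)
PI_LO <- 1e-6

theta_to_params <- function(theta, kind, estimate_a, a_fixed = 1) {
  pi_c <- max(stats::plogis(theta[1]) * PI_MAX, PI_LO)
  if (kind == "M2") {
    a <- if (estimate_a) theta[3] else a_fixed
    mixture_params("M2", pi_c = pi_c, sigma2 = exp(theta[2]), intercept_a = a)
  } else {
    s1 <- exp(theta[2]); s2 <- exp(theta[3])
    prop <- stats::plogis(theta[4])
    if (s1 < s2) { tmp <- s1; s1 <- s2; s2 <- tmp; prop <- 1 - prop }
    a <- if (estimate_a) theta[5] else a_fixed
    mixture_params("M3", pi_c = pi_c, sigma2_1 = s1, sigma2_2 = s2,
                   prop = prop, intercept_a = a)
  }
}

params_to_theta <- function(params, estimate_a) {
  th <- if (params$kind == "M2")
    c(stats::qlogis(min(max(params$pi_c / PI_MAX, 1e-9), 1 - 1e-9)),
      log(max(params$sigma2, 1e-12)))
  else
    c(stats::qlogis(min(max(params$pi_c / PI_MAX, 1e-9), 1 - 1e-9)),
      log(max(params$sigma2_1, 1e-12)), log(max(params$sigma2_2, 1e-12)),
      stats::qlogis(min(max(params$prop, 1e-6), 1 - 1e-6)))
  if (estimate_a) th <- c(th, params$intercept_a)
  th
}

# negative log-likelihood and analytic gradient on the free scale
neg_loglik_theta <- function(theta, z, n, kind, estimate_a, a_fixed = 1) {
  p <- theta_to_params(theta, kind, estimate_a, a_fixed)
  -sum(marginal_density(z, n, p, log = TRUE))
}

neg_grad_theta <- function(theta, z, n, kind, estimate_a, a_fixed = 1) {
  # gradient via chain rule; components share the structure
  # d logN(z;0,v)/dv = (z^2/v^2 - 1/v)/2
  pi_c <- stats::plogis(theta[1]) * PI_MAX
  a <- if (estimate_a) theta[length(theta)] else a_fixed
  if (kind == "M2") {
    s2 <- exp(theta[2])
    v0 <- a; v1 <- a + n * s2
    f0 <- dnorm(z, 0, sqrt(v0)); f1 <- dnorm(z, 0, sqrt(v1))
    den <- (1 - pi_c) * f0 + pi_c * f1
    dpi <- sum((f1 - f0) / den)
    dv1 <- pi_c * f1 * (z^2 / v1^2 - 1 / v1) / 2 / den
    ds2 <- sum(dv1 * n)
    da <- sum((1 - pi_c) * f0 * (z^2 / v0^2 - 1 / v0) / 2 / den + dv1)
    g <- c(dpi * pi_c * (1 - stats::plogis(theta[1])),  # d pi/d theta1
           ds2 * s2)
    if (estimate_a) g <- c(g, da)
  } else {
    s1 <- exp(theta[2]); s2 <- exp(theta[3])
    prop <- stats::plogis(theta[4])
    v0 <- a; v1 <- a + n * s1; v2 <- a + n * s2
    f0 <- dnorm(z, 0, sqrt(v0)); f1 <- dnorm(z, 0, sqrt(v1))
    f2 <- dnorm(z, 0, sqrt(v2))
    den <- (1 - pi_c) * f0 + pi_c * (prop * f1 + (1 - prop) * f2)
    dpi <- sum((prop * f1 + (1 - prop) * f2 - f0) / den)
    dprop <- sum(pi_c * (f1 - f2) / den)
    w1 <- pi_c * prop * f1 * (z^2 / v1^2 - 1 / v1) / 2 / den
    w2 <- pi_c * (1 - prop) * f2 * (z^2 / v2^2 - 1 / v2) / 2 / den
    ds1 <- sum(w1 * n); ds2 <- sum(w2 * n)
    da <- sum((1 - pi_c) * f0 * (z^2 / v0^2 - 1 / v0) / 2 / den + w1 + w2)
    g <- c(dpi * pi_c * (1 - stats::plogis(theta[1])),
           ds1 * s1, ds2 * s2,
           dprop * prop * (1 - prop))
    if (estimate_a) g <- c(g, da)
  }
  -g
}

default_init <- function(kind, z, n, a) {
  # moment start: excess z-variance split between a modest pi and sigma2
  excess <- max(mean(z^2) - a, 1e-4)
  pi0 <- 0.05
  s0 <- excess / (pi0 * mean(n))
  if (kind == "M2")
    mixture_params("M2", pi_c = pi0, sigma2 = s0, intercept_a = a)
  else
    mixture_params("M3", pi_c = pi0, sigma2_1 = 2 * s0, sigma2_2 = s0 / 2,
                   prop = 0.5, intercept_a = a)
}

#' Fit the point-normal mixture model to summary statistics
#'
#' Maximizes the marginal likelihood of the z-scores over the mixture
#' parameters. The default method is direct bounded maximization
#' (L-BFGS-B with analytic gradients on transformed parameters, so that
#' `pi_c` stays in `[1e-6, 0.5]`, variances stay nonnegative and the
#' intercept stays in `[0.8, 1.5]`). `method = "em"` runs a generalized EM
#' over latent component labels whose observed log-likelihood is
#' non-decreasing at every iteration, followed by the same bounded polish
#' (kept only if it improves the likelihood). For `kind = "M3"` the fit is
#' initialized from an M2 fit: its `pi_c` and `sigma2` seed both clusters
#' with `prop = 0.5`.
#'
#' @param table QC-filtered canonical summary-statistics tibble.
#' @param kind `"M2"` or `"M3"`.
#' @param init Optional [mixture_params()] start; for M3 this defaults to
#'   an internally computed M2 fit (or pass one via `m2_fit`).
#' @param m2_fit Optional `mixture_fit` used to initialize an M3 fit.
#' @param intercept `"estimate"` (default, bounds 0.8-1.5) or `"fixed"`
#'   (held at `a_fixed`).
#' @param a_fixed Intercept value under `intercept = "fixed"`.
#' @param method `"direct"` (default) or `"em"`.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param se Compute Hessian standard errors (default TRUE)?
#' @param M Reference-panel SNP count backing `pi_c`; defaults to the
#'   table's `M_reference` attribute (set by [qc_filter()]) or the number
#'   of fitted SNPs.
#' @return An object of class `mixture_fit`: fields `params`, `se`,
#'   `covariance`, `loglik`, `bic`, `n_snps_fit`, `M_reference`,
#'   `converged`, `n_iterations`, `degenerate`, `loglik_trace` (EM method
#'   only).
#' @export
fit_mixture <- function(table, kind = c("M2", "M3"), init = NULL,
                        m2_fit = NULL,
                        intercept = c("estimate", "fixed"), a_fixed = 1,
                        method = c("direct", "em"),
                        tol = 1e-8, max_iter = 2000, se = TRUE, M = NULL) {
  kind <- match.arg(kind)
  intercept <- match.arg(intercept)
  method <- match.arg(method)
  if (!nrow(table)) stop("empty summary-statistics table")
  z <- table$z; n <- table$n_eff
  estimate_a <- intercept == "estimate"
  M <- M %||% attr(table, "M_reference", exact = TRUE) %||% nrow(table)

  if (is.null(init)) {
    if (kind == "M3") {
      # Seed both clusters from the M2 fit. The equal-variance point is a
      # symmetric stationary point of the M3 likelihood (the gradient along
      # the split direction vanishes there), so a near-symmetric start never
      # separates the clusters; instead try several variance-preserving
      # asymmetric splits of the M2 solution and keep the best optimum.
      if (is.null(m2_fit))
        m2_fit <- fit_mixture(table, "M2", intercept = intercept,
                              a_fixed = a_fixed, method = method,
                              tol = tol, max_iter = max_iter,
                              se = FALSE, M = M)
      p2 <- m2_fit$params
      starts <- lapply(c(1.001, 4, 16), function(split)
        mixture_params("M3", pi_c = p2$pi_c,
                       sigma2_1 = p2$sigma2 * split,
                       sigma2_2 = p2$sigma2 / split,
                       prop = 0.5, intercept_a = p2$intercept_a))
      fits <- lapply(starts, function(st)
        fit_mixture(table, "M3", init = st, intercept = intercept,
                    a_fixed = a_fixed, method = method, tol = tol,
                    max_iter = max_iter, se = FALSE, M = M))
      best <- fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
      if (se) best <- standard_errors(best, table)
      return(best)
    }
    init <- default_init(kind, z, n, if (estimate_a) 1 else a_fixed)
  }

  trace <- numeric(0)
  n_iter <- 0L
  em_converged <- TRUE
  start <- init
  if (method == "em") {
    em <- em_fit(z, n, kind, start, estimate_a, a_fixed, tol, max_iter)
    start <- em$params; trace <- em$trace
    n_iter <- em$n_iterations; em_converged <- em$converged
  }

  theta0 <- params_to_theta(start, estimate_a)
  np <- length(theta0)
  lower <- rep(-30, np); upper <- rep(30, np)
  if (estimate_a) { lower[np] <- A_BOUNDS[1]; upper[np] <- A_BOUNDS[2] }
  opt <- stats::optim(theta0, neg_loglik_theta, gr = neg_grad_theta,
                      z = z, n = n, kind = kind,
                      estimate_a = estimate_a, a_fixed = a_fixed,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e4))
  params <- theta_to_params(opt$par, kind, estimate_a, a_fixed)
  ll <- -opt$value
  if (method == "em" && length(trace) && ll < trace[length(trace)]) {
    # polish failed to improve: keep the EM solution (monotone guarantee)
    params <- start
    ll <- trace[length(trace)]
  }
  converged <- if (method == "em") em_converged else opt$convergence == 0
  n_iter <- n_iter + if (method == "direct") opt$counts[["function"]] else 0L

  sig_min <- if (kind == "M2") params$sigma2
             else min(params$sigma2_1, params$sigma2_2)
  degenerate <- (params$pi_c <= PI_LO * 1.01) ||
    (sig_min * mean(n) < 1e-8 && params$pi_c >= PI_MAX * 0.999)

  d_free <- np
  fit <- structure(list(
    params = params,
    se = NULL, covariance = NULL, se_available = FALSE,
    loglik = ll,
    bic = -2 * ll + d_free * log(length(z)),
    n_free_params = d_free,
    n_snps_fit = length(z), M_reference = M,
    converged = converged, n_iterations = as.integer(n_iter),
    degenerate = degenerate, method = method,
    intercept_mode = intercept,
    loglik_trace = trace), class = "mixture_fit")
  if (se) fit <- standard_errors(fit, table)
  fit
}

# generalized EM: closed-form mixing weights, gradient M-step on variances
em_fit <- function(z, n, kind, params, estimate_a, a_fixed, tol, max_iter) {
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cv <- component_variances(params, n)
    K <- length(cv$w)
    f <- vapply(seq_len(K), function(k) dnorm(z, 0, sqrt(cv$v[k, ])),
                numeric(length(z)))
    den <- as.vector(f %*% cv$w)
    ll <- sum(log(den))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r <- sweep(f, 2, cv$w, `*`) / den  # responsibilities, columns = components
    pi_new <- min(max(1 - mean(r[, 1]), PI_LO), PI_MAX)
    prop_new <- if (kind == "M3") {
      s <- colMeans(r[, 2:3, drop = FALSE])
      if (sum(s) > 0) s[1] / sum(s) else 0.5
    } else NULL
    # M-step over variances: maximize expected complete-data log-likelihood
    # (responsibilities fixed); a few bounded quasi-Newton steps suffice (GEM)
    obj <- function(v) -em_q(v, z, n, r, kind, estimate_a, a_fixed)
    v0 <- em_vpack(params, kind, estimate_a)
    o <- stats::optim(v0, obj, method = "L-BFGS-B",
                      lower = em_vbounds(kind, estimate_a)$lo,
                      upper = em_vbounds(kind, estimate_a)$hi,
                      control = list(maxit = 10))
    params <- em_vunpack(o$par, kind, estimate_a, a_fixed, pi_new, prop_new)
  }
  list(params = params, trace = trace, n_iterations = it,
       converged = converged)
}

em_vpack <- function(params, kind, estimate_a) {
  v <- if (kind == "M2") params$sigma2
       else c(params$sigma2_1, params$sigma2_2)
  if (estimate_a) v <- c(v, params$intercept_a)
  v
}

em_vbounds <- function(kind, estimate_a) {
  nv <- if (kind == "M2") 1L else 2L
  lo <- rep(0, nv); hi <- rep(Inf, nv)
  if (estimate_a) { lo <- c(lo, A_BOUNDS[1]); hi <- c(hi, A_BOUNDS[2]) }
  list(lo = lo, hi = hi)
}

em_vunpack <- function(v, kind, estimate_a, a_fixed, pi_c, prop) {
  a <- if (estimate_a) v[length(v)] else a_fixed
  if (kind == "M2")
    mixture_params("M2", pi_c = pi_c, sigma2 = v[1], intercept_a = a)
  else {
    s1 <- v[1]; s2 <- v[2]
    if (s1 < s2) { tmp <- s1; s1 <- s2; s2 <- tmp; prop <- 1 - prop }
    mixture_params("M3", pi_c = pi_c, sigma2_1 = s1, sigma2_2 = s2,
                   prop = prop, intercept_a = a)
  }
}

em_q <- function(v, z, n, r, kind, estimate_a, a_fixed) {
  a <- if (estimate_a) v[length(v)] else a_fixed
  q <- sum(r[, 1] * dnorm(z, 0, sqrt(a), log = TRUE))
  if (kind == "M2") {
    q <- q + sum(r[, 2] * dnorm(z, 0, sqrt(a + n * v[1]), log = TRUE))
  } else {
    q <- q + sum(r[, 2] * dnorm(z, 0, sqrt(a + n * v[1]), log = TRUE)) +
      sum(r[, 3] * dnorm(z, 0, sqrt(a + n * v[2]), log = TRUE))
  }
  q
}

# natural-scale parameter vector entering the Hessian
fit_par_vector <- function(fit) {
  p <- fit$params
  est_a <- fit$intercept_mode == "estimate"
  if (p$kind == "M2") {
    v <- c(pi_c = p$pi_c, sigma2 = p$sigma2)
  } else {
    v <- c(pi_c = p$pi_c, sigma2_1 = p$sigma2_1, sigma2_2 = p$sigma2_2,
           prop = p$prop)
  }
  if (est_a) v <- c(v, intercept_a = p$intercept_a)
  v
}

par_vector_to_params <- function(v, kind, a_fixed = 1) {
  a <- if ("intercept_a" %in% names(v)) v[["intercept_a"]] else a_fixed
  if (kind == "M2")
    mixture_params("M2", pi_c = v[["pi_c"]], sigma2 = v[["sigma2"]],
                   intercept_a = a)
  else {
    s1 <- v[["sigma2_1"]]; s2 <- v[["sigma2_2"]]; pr <- v[["prop"]]
    if (s1 < s2) { tmp <- s1; s1 <- s2; s2 <- tmp; pr <- 1 - pr }
    mixture_params("M3", pi_c = v[["pi_c"]], sigma2_1 = s1, sigma2_2 = s2,
                   prop = pr, intercept_a = a)
  }
}

#' Standard errors of fitted mixture parameters
#'
#' Computes the parameter covariance as the inverse of the negative
#' numerical Hessian of the log-likelihood at the optimum (central
#' differences with relative step 1e-4, on the natural parameter scale).
#' When the Hessian is not positive definite — typically when a parameter
#' sits on a bound — the covariance and standard errors are flagged
#' unavailable rather than reported; downstream comparisons drop such
#' traits.
#'
#' @param fit A `mixture_fit`.
#' @param table The table the model was fitted to.
#' @return The fit with `covariance`, `se` and `se_available` filled in.
#' @export
standard_errors <- function(fit, table) {
  stopifnot(inherits(fit, "mixture_fit"))
  v0 <- fit_par_vector(fit)
  kind <- fit$params$kind
  a_fx <- fit$params$intercept_a
  ll_fun <- function(v) {
    p <- tryCatch(par_vector_to_params(v, kind, a_fx), error = function(e) NULL)
    if (is.null(p)) return(NA_real_)
    sum(marginal_density(table$z, table$n_eff, p, log = TRUE))
  }
  H <- numeric_hessian(ll_fun, v0, rel_step = 1e-4)
  cov <- tryCatch({
    if (any(!is.finite(H))) stop("non-finite Hessian")
    ch <- chol(-H)  # errors unless -H is positive definite
    chol2inv(ch)
  }, error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) <= 0)) {
    fit$covariance <- NULL
    fit$se <- setNames(rep(NA_real_, length(v0)), names(v0))
    fit$se_available <- FALSE
  } else {
    dimnames(cov) <- list(names(v0), names(v0))
    fit$covariance <- cov
    fit$se <- sqrt(diag(cov))
    fit$se_available <- TRUE
  }
  fit
}

# central-difference Hessian with per-coordinate relative steps
numeric_hessian <- function(f, x, rel_step = 1e-4) {
  p <- length(x)
  h <- pmax(abs(x), 1e-8) * rel_step
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in seq((i + 1), p)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Bayesian information criterion of a mixture fit
#'
#' `-2 * loglik + d * log(n_snps_fit)` with `d` the number of free
#' parameters (M2: 3 with estimated intercept; M3: 5).
#'
#' @param fit A converged `mixture_fit`.
#' @return Scalar BIC.
#' @export
model_bic <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  -2 * fit$loglik + fit$n_free_params * log(fit$n_snps_fit)
}

#' Choose between the two- and three-component models
#'
#' Returns `"M2"` if the M3 variance ratio `sigma2_1 / sigma2_2` is below
#' `ratio_cutoff` (default 5) or if the M2 BIC is lower than the M3 BIC;
#' otherwise `"M3"`. A non-converged M3 fit always yields `"M2"`. A zero
#' `sigma2_2` makes the ratio infinite, so the decision falls to BIC alone.
#'
#' @param fit_m2,fit_m3 `mixture_fit` objects of the respective kinds.
#' @param ratio_cutoff Variance-ratio threshold (default 5).
#' @return `"M2"` or `"M3"`.
#' @export
select_model <- function(fit_m2, fit_m3, ratio_cutoff = 5) {
  stopifnot(inherits(fit_m2, "mixture_fit"), inherits(fit_m3, "mixture_fit"),
            fit_m2$params$kind == "M2", fit_m3$params$kind == "M3")
  if (!fit_m3$converged) return("M2")
  ratio <- if (fit_m3$params$sigma2_2 == 0) Inf
           else fit_m3$params$sigma2_1 / fit_m3$params$sigma2_2
  if (ratio < ratio_cutoff || model_bic(fit_m2) < model_bic(fit_m3))
    "M2" else "M3"
}

#' Expected QQ curve and confidence band under a fitted model
#'
#' Simulates `n_draws` z-vectors from the fitted marginal mixture matched
#' to the table's per-SNP effective sample sizes, converts them to
#' two-sided p-values and ranks them. The expected curve is the per-rank
#' mean of -log10(p) across draws and the band spans the corresponding
#' lower/upper quantiles (10th/90th percentile for the default 80% band).
#'
#' @param fit A converged `mixture_fit`.
#' @param table The observed table (supplies `z`, `n_eff` and the observed
#'   curve).
#' @param n_draws Number of simulated replicates (minimum 20).
#' @param seed Integer seed; results are deterministic given it.
#' @param band Band coverage (default 0.80).
#' @return A list of class `qq_data`: `observed_neglog10p` (sorted
#'   descending), `expected_neglog10p`, `band_lo`, `band_hi`, `n_draws`,
#'   `seed`.
#' @export
qq_expected <- function(fit, table, n_draws = 200, seed = 1, band = 0.80) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (n_draws < 20) stop("n_draws must be at least 20 for a stable band")
  stopifnot(is_fraction(band))
  m <- nrow(table)
  obs <- sort(-log10(two_sided_p(table$z)), decreasing = TRUE)
  sims <- withr::with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      zi <- simulate_z(fit$params, table$n_eff)
      sort(-log10(two_sided_p(zi)), decreasing = TRUE)
    }, numeric(m))
  })
  qs <- c((1 - band) / 2, 1 - (1 - band) / 2)
  structure(list(
    observed_neglog10p = obs,
    expected_neglog10p = rowMeans(sims),
    band_lo = apply(sims, 1, quantile, probs = qs[1], names = FALSE),
    band_hi = apply(sims, 1, quantile, probs = qs[2], names = FALSE),
    n_draws = n_draws, seed = seed), class = "qq_data")
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))

# one z-vector from the fitted marginal mixture (uses the current RNG state)
simulate_z <- function(params, n_eff) {
  m <- length(n_eff)
  cv <- component_variances(params, n_eff)
  comp <- sample.int(length(cv$w), m, replace = TRUE, prob = cv$w)
  v <- cv$v[cbind(comp, seq_len(m))]
  rnorm(m, 0, sqrt(v))
}

#' @export
print.mixture_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("%s mixture fit: %d SNPs (M = %g reference)\n",
              p$kind, x$n_snps_fit, x$M_reference))
  if (p$kind == "M2")
    cat(sprintf("  pi_c = %.4g  sigma2 = %.4g  a = %.4g\n",
                p$pi_c, p$sigma2, p$intercept_a))
  else
    cat(sprintf("  pi_c = %.4g  sigma2_1 = %.4g  sigma2_2 = %.4g  prop = %.3g  a = %.4g\n",
                p$pi_c, p$sigma2_1, p$sigma2_2, p$prop, p$intercept_a))
  cat(sprintf("  loglik = %.2f  BIC = %.2f  converged = %s  SEs %s\n",
              x$loglik, model_bic(x), x$converged,
              if (x$se_available) "available" else "unavailable"))
  invisible(x)
}

#' Serialize a mixture fit to JSON
#'
#' @param fit A `mixture_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(kind = fit$params$kind,
              params = fit$params[!vapply(fit$params, is.null, logical(1))],
              se = as.list(fit$se),
              covariance = fit$covariance,
              se_available = fit$se_available,
              loglik = fit$loglik, bic = model_bic(fit),
              n_snps_fit = fit$n_snps_fit, M_reference = fit$M_reference,
              converged = fit$converged, n_iterations = fit$n_iterations)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
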