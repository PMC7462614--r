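#' Build an unfolded site frequency spectrum from polarized sites
#'
#' Polymorphic sites contribute at derived count round(daf * n) (clamped
#' to 1..n-1); fixed-status sites (divergent and nearly fixed) contribute
#' to the fixed (divergence) class.
#'
#' @param polarized data.table with `daf` and `status` (optionally
#'   pre-filtered to one degeneracy class).
#' @param n haploid sample size of the spectrum.
#' @param class label stored with the spectrum (e.g. `"synonymous"`).
#' @return object of class `sfs`: `counts` (named vector over 1..n-1),
#'   `fixed`, `n`, `class`.
#' @export
build_sfs <- function(polarized, n, class = "unlabelled") {
  stopifnot(n >= 2)
  pol <- data.table::as.data.table(polarized)
  counts <- rep(0, n - 1)
  poly <- pol[status == "polymorphic"]
  if (nrow(poly)) {
    i <- pmin(pmax(round(poly$daf * n), 1), n - 1)
    tb <- table(factor(i, levels = seq_len(n - 1)))
    counts <- as.numeric(tb)
  }
  fixed <- nrow(pol[status == "fixed"])
  structure(list(counts = stats::setNames(counts, seq_len(n - 1)),
                 fixed = fixed, n = as.integer(n), class = class),
            class = "sfs")
}

#' Construct an SFS object from raw counts
#' @param counts numeric vector over derived counts 1..n-1.
#' @param fixed number of fixed derived sites.
#' @param class label.
#' @return an `sfs` object.
#' @export
as_sfs <- function(counts, fixed = 0, class = "unlabelled") {
  n <- length(counts) + 1L
  structure(list(counts = stats::setNames(as.numeric(counts),
                                          seq_len(n - 1)),
                 fixed = fixed, n = n, class = class),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("sfs (%s): n = %d, %.0f polymorphic, %.0f fixed\n",
              x$class, x$n, sum(x$counts), x$fixed))
  invisible(x)
}

#' Hypergeometric projection of an SFS to a smaller sample size
#'
#' Expected downsampling: a site at derived count j of n contributes
#' P\[Hypergeometric(n, j, m) = i\] to class i of the projected spectrum.
#' Mass landing on the monomorphic classes 0 and m is dropped from the
#' polymorphic spectrum and recorded separately; the fixed class is
#' carried over unchanged.
#'
#' @param sfs an `sfs` object at sample size n.
#' @param n_target target size m (2 <= m <= n; default 10).
#' @return an `sfs` at size m with extra fields `dropped_zero` and
#'   `dropped_fixed` (the projected mass at counts 0 and m).
#' @export
project_sfs <- function(sfs, n_target = 10) {
  stopifnot(inherits(sfs, "sfs"))
  n <- sfs$n
  m <- as.integer(n_target)
  if (m < 2) stop("n_target must be >= 2")
  if (m > n) stop("n_target must not exceed the native sample size")
  if (m == n) {
    out <- sfs
    out$dropped_zero <- 0
    out$dropped_fixed <- 0
    return(out)
  }
  proj <- rep(0, m + 1)  # classes 0..m
  for (j in seq_len(n - 1)) {
    cj <- sfs$counts[[j]]
    if (cj == 0) next
    i <- 0:m
    proj <- proj + cj * stats::dhyper(i, j, n - j, m)
  }
  out <- as_sfs(proj[2:m], fixed = sfs$fixed, class = sfs$class)
  out$dropped_zero <- proj[1]
  out$dropped_fixed <- proj[m + 1]
  out
}

# Wright-Fisher sojourn density factor under genic selection:
# H(x; S) = (1 - exp(-S(1-x))) / (x(1-x)(1 - exp(-S))), neutral limit 1/x.
# The ratio part is computed in the overflow-safe form
# (exp(Sx) - exp(S)) / (1 - exp(S)).
.sfs_ratio <- function(x, S) {
  if (S == 0) return(1 - x)
  if (S < 0) (exp(S * x) - exp(S)) / (1 - exp(S))
  else expm1(-S * (1 - x)) / expm1(-S)
}

#' Expected site frequency spectrum under selection
#'
#' Poisson-random-field expectation for a sample of n chromosomes:
#' E\[F_i\] = theta_L * C(n,i) * Int_0^1 H(x; S) x^i (1-x)^(n-i) dx with
#' H the standard sojourn-time factor (neutral limit H = 1/x, giving the
#' theta_L / i spectrum). S = 4 N_e s is the scaled selection
#' coefficient. For S below -500 the boundary-layer asymptotic
#' E\[F_i\] ~ theta_L * C(n,i) * (i-1)! / |S|^i is used.
#'
#' @param S scaled selection coefficient (scalar).
#' @param theta_L total mutation supply of the class (theta per site
#'   times number of sites).
#' @param n sample size in chromosomes.
#' @return numeric vector E\[F_1\] .. E\[F_(n-1)\].
#' @export
expected_sfs <- function(S, theta_L, n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  if (S == 0) return(theta_L / i)
  if (S < -500) {
    return(theta_L * choose(n, i) * gamma(i) / abs(S)^i)
  }
  vapply(i, function(ii) {
    f <- function(x) .sfs_ratio(x, S) * x^(ii - 1) * (1 - x)^(n - ii - 1)
    theta_L * choose(n, ii) *
      stats::integrate(f, 0, 1, rel.tol = 1e-9, abs.tol = 0)$value
  }, numeric(1))
}

# Interpolation grid of expected spectra over |S|, built once per sample
# size and cached: rows = grid points, cols = classes 1..n-1, values on
# the log scale for smooth splines in log|S|.
.sfs_grid <- function(n) {
  key <- paste0("sfs_grid_", n)
  g <- get0(key, envir = .poolpopgen_env)
  if (!is.null(g)) return(g)
  logS <- seq(log(1e-4), log(1e5), length.out = 140)
  Svals <- -exp(logS)
  E <- t(vapply(Svals, function(S) expected_sfs(S, 1, n),
                numeric(n - 1)))
  funs <- lapply(seq_len(n - 1), function(j)
    stats::splinefun(logS, log(E[, j]), method = "natural"))
  g <- list(logS = logS, funs = funs, n = n,
            neutral = 1 / seq_len(n - 1))
  assign(key, g, envir = .poolpopgen_env)
  g
}

# Expected spectrum (theta_L = 1) for a vector of negative S, via the
# cached spline grid; |S| below the grid floor snaps to neutral.
.expected_sfs_interp <- function(S, n) {
  g <- .sfs_grid(n)
  out <- matrix(0, nrow = length(S), ncol = n - 1)
  a <- pmin(pmax(abs(S), 1e-4), 1e5)
  la <- log(a)
  tiny <- abs(S) < 1e-4
  for (j in seq_len(n - 1)) {
    out[, j] <- exp(g$funs[[j]](la))
    out[tiny, j] <- g$neutral[j]
  }
  out
}

#' Fit a gamma distribution of fitness effects to projected spectra
#'
#' Maximizes the Poisson composite likelihood of the non-synonymous SFS
#' under a gamma distribution of the scaled deleterious effect -S = 4 N_e
#' |s| (parameters: shape and mean), with per-class mutation-supply
#' nuisance parameters profiled out analytically and the synonymous
#' spectrum fitted as neutral. Two model variants are available: a pure
#' deleterious gamma (`"del"`) and a mixture with a neutral point mass
#' (`"del_neut"`). The gamma is discretized into `n_classes` quantile
#' classes and expected spectra come from a cached spline interpolation
#' of the Poisson-random-field integrals.
#'
#' @param sfs_syn,sfs_nonsyn `sfs` objects at a common sample size.
#' @param model `"del"` or `"del_neut"`.
#' @param n_classes gamma discretization classes (default 64).
#' @param n_boot Poisson parametric bootstrap replicates for confidence
#'   intervals (default 200; 0 disables).
#' @param conf confidence level.
#' @return object of class `dfe_fit`: `model`, `shape`, `mean_S` (mean of
#'   -S = 4 N_e |s|), `p_neutral`, `theta_syn`, `theta_nonsyn`, `logLik`,
#'   `AIC`, `n_params`, `convergence`, and bootstrap `ci` (a matrix) when
#'   requested.
#' @export
fit_gamma_dfe <- function(sfs_syn, sfs_nonsyn, model = c("del", "del_neut"),
                          n_classes = 64, n_boot = 200, conf = 0.95) {
  model <- match.arg(model)
  stopifnot(inherits(sfs_syn, "sfs"), inherits(sfs_nonsyn, "sfs"))
  if (sfs_syn$n != sfs_nonsyn$n)
    stop("spectra must be projected to a common sample size")
  n <- sfs_syn$n
  i <- seq_len(n - 1)
  Fs <- as.numeric(sfs_syn$counts)
  Fn <- as.numeric(sfs_nonsyn$counts)
  if (sum(Fs) == 0 || sum(Fn) == 0) stop("empty spectrum")

  # neutral (synonymous) theta: Poisson MLE under the theta/i spectrum
  theta_syn <- sum(Fs) / sum(1 / i)
  ll_syn <- sum(Fs * log(theta_syn / i) - theta_syn / i)

  pois_ll <- function(obs, lam) sum(obs * log(lam) - lam)

  fit_one <- function(Fn) {
    obj <- function(par) {
      shape <- exp(par[1])
      meanS <- exp(par[2])
      pneut <- if (model == "del_neut") stats::plogis(par[3]) else 0
      q <- stats::qgamma((seq_len(n_classes) - 0.5) / n_classes,
                         shape = shape, scale = meanS / shape)
      Em <- .expected_sfs_interp(-q, n)
      e <- (1 - pneut) * colMeans(Em) + pneut / i
      theta_ns <- sum(Fn) / sum(e)
      -pois_ll(Fn, theta_ns * e)
    }
    start <- if (model == "del_neut") c(log(0.5), log(100), 0)
      else c(log(0.5), log(100))
    lower <- c(log(1e-3), log(1e-2), -10)[seq_along(start)]
    upper <- c(log(100), log(1e5), 10)[seq_along(start)]
    opt <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500, factr = 1e4))
    shape <- exp(opt$par[1])
    meanS <- exp(opt$par[2])
    pneut <- if (model == "del_neut") stats::plogis(opt$par[3]) else 0
    q <- stats::qgamma((seq_len(n_classes) - 0.5) / n_classes,
                       shape = shape, scale = meanS / shape)
    e <- (1 - pneut) * colMeans(.expected_sfs_interp(-q, n)) + pneut / i
    theta_ns <- sum(Fn) / sum(e)
    list(shape = shape, mean_S = meanS, p_neutral = pneut,
         theta_nonsyn = theta_ns, ll = -opt$value,
         convergence = opt$convergence)
  }

  pt <- fit_one(Fn)
  if (pt$shape <= 1.01e-3 || pt$shape >= 99 ||
      pt$mean_S <= 1.01e-2 || pt$mean_S >= 0.99e5)
    warning("DFE parameter estimate pinned to the boundary; ",
            "the spectrum may be uninformative")
  # parameters: shape, mean, (p_neutral), theta_nonsyn, theta_syn
  k <- if (model == "del_neut") 5L else 4L
  ll <- pt$ll + ll_syn
  ci <- NULL
  if (n_boot > 0) {
    bs <- matrix(NA_real_, nrow = n_boot, ncol = 2,
                 dimnames = list(NULL, c("shape", "mean_S")))
    for (r in seq_len(n_boot)) {
      br <- try(fit_one(stats::rpois(n - 1, pmax(Fn, 1e-9))), silent = TRUE)
      if (!inherits(br, "try-error"))
        bs[r, ] <- c(br$shape, br$mean_S)
    }
    pr <- c((1 - conf) / 2, (1 + conf) / 2)
    ci <- apply(bs, 2, stats::quantile, probs = pr, na.rm = TRUE)
  }
  structure(list(model = model, shape = pt$shape, mean_S = pt$mean_S,
                 p_neutral = pt$p_neutral, theta_syn = theta_syn,
                 theta_nonsyn = pt$theta_nonsyn, logLik = ll,
                 AIC = 2 * k - 2 * ll, n_params = k,
                 convergence = pt$convergence, ci = ci),
            class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("dfe_fit [%s]: shape = %.3f, mean 4Ns = -%.1f", x$model,
              x$shape, x$mean_S))
  if (x$model == "del_neut")
    cat(sprintf(", p_neutral = %.3f", x$p_neutral))
  cat(sprintf("\n  logLik = %.2f, AIC = %.2f (%d parameters)\n",
              x$logLik, x$AIC, x$n_params))
  invisible(x)
}

#' Model choice among DFE fits by AIC
#'
#' @param fits list of `dfe_fit` objects.
#' @return the fit with the lowest AIC; on exact ties the one with fewest
#'   parameters.
#' @export
compare_models_aic <- function(fits) {
  stopifnot(length(fits) >= 1)
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  k <- vapply(fits, function(f) f$n_params, numeric(1))
  fits[[order(aic, k)[1]]]
}
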