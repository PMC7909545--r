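#' Iterative Spearman + VIF collinearity screen
#'
#' Mirrors the usual two-stage screen: (1) while any predictor pair has
#' |Spearman rho| at or above `r_max`, take the worst pair and drop the
#' member with the larger variance inflation factor; (2) while any VIF is
#' at or above `vif_max`, drop the largest.  VIFs are the diagonal of the
#' inverse correlation matrix of the surviving predictors.
#'
#' @param X A data frame of numeric predictors (an optional `cell` column
#'   is ignored).
#' @param r_max Pairwise absolute Spearman threshold (default 0.7).
#' @param vif_max VIF threshold (default 10).
#' @return Character vector of retained predictor names, in input order.
#' @export
vif_screen <- function(X, r_max = 0.7, vif_max = 10) {
  stopifnot(is.data.frame(X))
  X <- X[, setdiff(names(X), "cell"), drop = FALSE]
  if (ncol(X) < 2L) stop("need at least 2 predictors", call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(names(X)[sds == 0], collapse = ", "), call. = FALSE)
  keep <- names(X)

  vifs <- function(cols) {
    r <- stats::cor(X[cols])
    inv <- tryCatch(solve(r), error = function(e)
      solve(r + diag(1e-10, nrow(r))))   # exact duplicates: huge finite VIF
    diag(inv)
  }
  repeat {
    rho <- stats::cor(X[keep], method = "spearman")
    diag(rho) <- 0
    if (max(abs(rho)) < r_max || length(keep) < 2L) break
    worst <- which(abs(rho) == max(abs(rho)), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    v <- vifs(keep)
    drop <- pair[which.max(v[pair])]
    keep <- setdiff(keep, drop)
  }
  repeat {
    if (length(keep) < 2L) break
    v <- vifs(keep)
    if (max(v) < vif_max) break
    keep <- setdiff(keep, names(v)[which.max(v)])
  }
  names(X)[names(X) %in% keep]
}

#' Standardize predictors to mean 0, sd 1
#'
#' @param X Data frame of predictors (`cell` column passed through).
#' @return A tibble with every non-`cell` column centred and scaled.
#' @export
standardize_predictors <- function(X) {
  X <- tibble::as_tibble(X)
  num <- setdiff(names(X), "cell")
  X[num] <- lapply(X[num], function(v) as.numeric(scale(v)))
  X
}

#' Symmetrized, row-standardized k-nearest-neighbour spatial weights
#'
#' Binary kNN adjacency on planar coordinates, symmetrized by union (i is
#' a neighbour of j if either is among the other's k nearest), then
#' row-standardized so each row sums to 1.
#'
#' @param coords Data frame or matrix with `x`, `y` columns (or two
#'   numeric columns).
#' @param k Number of nearest neighbours (`1 <= k < n`).
#' @return A list with `W` (n x n row-standardized matrix), `B` (binary
#'   symmetric adjacency) and `k`.
#' @export
knn_weights <- function(coords, k) {
  xy <- as.matrix(if (is.data.frame(coords))
    coords[, intersect(c("x", "y"), names(coords))] else coords)
  n <- nrow(xy)
  if (k < 1L || k >= n) stop("need 1 <= k < n", call. = FALSE)
  d <- as.matrix(stats::dist(xy))
  if (any(d[upper.tri(d)] == 0))
    stop("duplicate coordinates", call. = FALSE)
  diag(d) <- Inf
  B <- matrix(0L, n, n)
  for (i in seq_len(n))
    B[i, order(d[i, ])[seq_len(k)]] <- 1L
  B <- (B | t(B)) * 1L
  W <- B / rowSums(B)
  list(W = W, B = B, k = as.integer(k))
}

#' Maximum-likelihood spatial autoregressive error model
#'
#' Fits `y = X beta + u`, `u = lambda W u + e`, `e ~ N(0, sigma^2 I)`.
#' `lambda` is found by maximizing the profile log-likelihood, using the
#' exact log-determinant of `(I - lambda W)` from the eigenvalues of `W`
#' (computed once); `beta` and `sigma^2` follow by generalized least
#' squares at the optimum.  With `lambda = 0` the model collapses to
#' ordinary least squares.  Reported alongside: AICc with
#' `q = p + 2` parameters (`lambda` and `sigma^2` count), and the
#' Nagelkerke pseudo-R-squared `GR^2` against the intercept-only
#' non-spatial Gaussian model, rescaled to its attainable maximum.
#'
#' @param y Numeric response (or data frame with `cell` + one column).
#' @param X Data frame/matrix of standardized predictors (no intercept
#'   column; one is added; `cell` column ignored).
#' @param W Row-standardized weights matrix, or the list from
#'   [knn_weights()].
#' @param lambda_tol Convergence tolerance of the lambda search.
#' @param fixed_lambda Optional fixed value of lambda (skips the
#'   profile-likelihood search; 0 gives the non-spatial GLS = OLS fit).
#' @return A `sar_fit` object; see [tidy.sar_fit()] / [glance.sar_fit()].
#' @export
fit_sar_error <- function(y, X, W, lambda_tol = 1e-8, fixed_lambda = NULL) {
  k_used <- NA_integer_
  if (is.list(W) && !is.matrix(W)) { k_used <- W$k %||% NA_integer_; W <- W$W }
  if (is.data.frame(y)) y <- y[[setdiff(names(y), "cell")[1]]]
  y <- as.numeric(y)
  if (is.data.frame(X)) X <- as.matrix(X[, setdiff(colnames(X), "cell"),
                                         drop = FALSE])
  n <- length(y)
  if (!is.null(X)) stopifnot(nrow(X) == n)
  stopifnot(nrow(W) == n)
  Xd <- cbind(`(Intercept)` = rep(1, n), X)
  p <- ncol(Xd)
  if (n <= p + 2) stop("too few observations for p predictors", call. = FALSE)
  if (qr(Xd)$rank < p) stop("near-singular design matrix", call. = FALSE)

  ev <- eigen(W, only.values = TRUE)$values
  if (is.complex(ev)) ev <- Re(ev)   # row-standardized similar-to-symmetric
  lo <- if (min(ev) < 0) 1 / min(ev) + 1e-9 else -1 + 1e-9
  hi <- 1 / max(ev) - 1e-9

  prof <- function(lambda) {
    A <- diag(n) - lambda * W
    ys <- as.numeric(A %*% y); Xs <- A %*% Xd
    fit <- stats::lm.fit(Xs, ys)
    rss <- sum(fit$residuals^2)
    sig2 <- rss / n
    ld <- sum(log(1 - lambda * ev))
    ll <- -n / 2 * (log(2 * pi * sig2) + 1) + ld
    if (!is.finite(ll)) return(-1e300)
    ll
  }
  if (is.null(fixed_lambda)) {
    opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = lambda_tol)
    lambda <- opt$maximum
    if (!is.finite(opt$objective) || opt$objective <= -1e299)
      stop("non-finite likelihood across the lambda interval", call. = FALSE)
    # prefer exactly 0 when numerically indistinguishable
    if (abs(lambda) < 10 * lambda_tol && prof(0) >= opt$objective - 1e-9)
      lambda <- 0
  } else {
    lambda <- fixed_lambda
    if (lambda < lo || lambda > hi)
      stop("fixed_lambda outside the feasible interval", call. = FALSE)
  }

  A <- diag(n) - lambda * W
  ys <- as.numeric(A %*% y)
  Xs <- A %*% Xd
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  res_s <- fit$residuals                      # spatially filtered residuals
  sig2 <- sum(res_s^2) / n
  logL <- -n / 2 * (log(2 * pi * sig2) + 1) + sum(log(1 - lambda * ev))

  # asymptotic z-tests for beta from the GLS covariance
  XtX <- crossprod(Xs)
  se <- sqrt(diag(sig2 * chol2inv(chol(XtX))) * n / (n - p))
  z <- beta / se

  # intercept-only, non-spatial Gaussian reference likelihood
  s0 <- sum((y - mean(y))^2) / n
  logL0 <- -n / 2 * (log(2 * pi * s0) + 1)
  gr2 <- (1 - exp(-2 / n * (logL - logL0))) / (1 - exp(2 / n * logL0))

  q <- p + 2
  aic <- -2 * logL + 2 * q
  aicc <- aic + 2 * q * (q + 1) / (n - q - 1)

  structure(
    list(coefficients = beta, se = se, z = z,
         lambda = lambda, sigma2 = sig2, logLik = logL, logLik0 = logL0,
         AIC = aic, AICc = aicc, GR2 = gr2,
         residuals = as.numeric(y - Xd %*% beta),          # response scale
         filtered_residuals = as.numeric(res_s),
         fitted = as.numeric(Xd %*% beta),
         n = n, p = p, k = k_used,
         lambda_interval = c(lo, hi)),
    class = "sar_fit"
  )
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("<sar_fit> n = %d, lambda = %.4f, GR2 = %.3f, AICc = %.2f\n",
              x$n, x$lambda, x$GR2, x$AICc))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy SAR coefficients
#'
#' @param x A `sar_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` and significance `stars` (`*` p < 0.05, `**` p < 0.001).
#' @method tidy sar_fit
#' @export
tidy.sar_fit <- function(x, ...) {
  p <- 2 * stats::pnorm(-abs(x$z))
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se), statistic = unname(x$z),
                 p.value = unname(p),
                 stars = ifelse(p < 0.001, "**",
                                ifelse(p < 0.05, "*", "")))
}

#' @rdname tidy.sar_fit
#' @method glance sar_fit
#' @export
glance.sar_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, sigma2 = x$sigma2, logLik = x$logLik,
                 AIC = x$AIC, AICc = x$AICc, GR2 = x$GR2, n = x$n,
                 k = x$k)
}

#' AICc neighbour-count selection for the SAR-error model
#'
#' Fits one SAR-error model per candidate k (kNN weights built from the
#' coordinates) and returns the fit with the lowest AICc; exact ties go
#' to the smaller k.
#'
#' @param y,X As in [fit_sar_error()].
#' @param coords Planar cell coordinates (data frame with `x`, `y`).
#' @param k_candidates Integer vector of neighbour counts (default 1:8).
#' @return The winning `sar_fit`, with `k` set and an `aicc_path`
#'   attribute (tibble `k`, `AICc`).
#' @export
select_sar <- function(y, X, coords, k_candidates = 1:8) {
  stopifnot(length(k_candidates) >= 1L)
  fits <- list(); errs <- character()
  for (k in k_candidates) {
    f <- tryCatch(fit_sar_error(y, X, knn_weights(coords, k)),
                  error = function(e) e)
    if (inherits(f, "error")) errs <- c(errs, sprintf("k=%d: %s", k,
                                                      conditionMessage(f)))
    else fits[[as.character(k)]] <- f
  }
  if (!length(fits))
    stop("all SAR fits failed: ", paste(errs, collapse = "; "),
         call. = FALSE)
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  best <- fits[[which.min(aicc)]]   # which.min takes the first on ties
  attr(best, "aicc_path") <- tibble::tibble(
    k = as.integer(names(fits)), AICc = unname(aicc))
  best
}

#' Moran's I correlogram of residuals
#'
#' Splits the pairwise-distance range into `n_classes` equal-width bins
#' and computes Moran's I within each bin with binary in-bin weights.
#' Bins with no pairs are reported with `NA`.  Under spatial independence
#' I is centred on `-1/(n-1)` in every class.
#'
#' @param residuals Numeric vector (constant input is an error).
#' @param coords Planar coordinates (data frame with `x`, `y`).
#' @param n_classes Number of distance classes (default 10).
#' @return A tibble with `class`, `d_lower`, `d_upper`, `n_pairs`,
#'   `moran_i`, `expectation`.
#' @export
moran_correlogram <- function(residuals, coords, n_classes = 10) {
  z <- as.numeric(residuals)
  n <- length(z)
  stopifnot(n >= 2L, n_classes >= 1L)
  if (stats::sd(z) == 0)
    stop("constant residuals: Moran's I undefined", call. = FALSE)
  xy <- as.matrix(if (is.data.frame(coords))
    coords[, intersect(c("x", "y"), names(coords))] else coords)
  d <- as.matrix(stats::dist(xy))
  brk <- seq(0, max(d), length.out = n_classes + 1L)
  zc <- z - mean(z)
  denom <- sum(zc^2)
  out <- purrr::map_dfr(seq_len(n_classes), function(b) {
    w <- d > brk[b] & d <= brk[b + 1L]
    diag(w) <- FALSE
    s0 <- sum(w)
    i <- if (s0 == 0) NA_real_ else
      n / s0 * sum(w * outer(zc, zc)) / denom
    tibble::tibble(class = b, d_lower = brk[b], d_upper = brk[b + 1L],
                   n_pairs = s0 / 2, moran_i = i,
                   expectation = -1 / (n - 1))
  })
  out
}
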