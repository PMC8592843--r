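#' Fit a two-Gaussian mixture to cell lengths by expectation-maximization
#'
#' Separates the short (meristem) and long (elongation-zone) cell-length
#' populations within one tissue x condition stratum. The EM iteration is
#' run on raw lengths until the log-likelihood change falls below `tol` or
#' `max_iter` is reached; components are relabeled afterwards so the short
#' component has the smaller mean.
#'
#' @param lengths Numeric vector of cell lengths (um); at least 10 finite
#'   positive values.
#' @param init_strategy `"median"` (default: split at the median and take
#'   each half's moments) or `"quantile"` (split at the 25%/75% quantile
#'   means).
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum number of EM iterations.
#' @return An object of class `length_mixture` with fields `mean_short`,
#'   `mean_long`, `sd_short`, `sd_long`, `weight_short`, `loglik`,
#'   `loglik_trace`, `n_iter` and `converged`.
#' @export
fit_length_mixture <- function(lengths, init_strategy = c("median",
                                                          "quantile"),
                               tol = 1e-8, max_iter = 500) {
  init_strategy <- match.arg(init_strategy)
  x <- as.numeric(lengths)
  if (length(x) < 10) stop("need at least 10 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("lengths must be finite and positive", call. = FALSE)
  }
  if (sd(x) < 1e-8) {
    stop("degenerate fit: zero length variance; consider fewer components",
         call. = FALSE)
  }
  split_at <- if (init_strategy == "median") stats::median(x) else
    mean(quantile(x, c(0.25, 0.75)))
  lo <- x[x <= split_at]; hi <- x[x > split_at]
  if (length(hi) == 0) { hi <- lo[lo >= stats::median(lo)] }
  mu <- c(mean(lo), mean(hi))
  s <- pmax(c(sd(lo), sd(hi)), sd(x) / 20, 1e-6)
  s[is.na(s)] <- sd(x) / 4
  w <- length(lo) / length(x)
  w <- min(max(w, 0.05), 0.95)

  loglik_of <- function(w, mu, s) {
    sum(log(w * dnorm(x, mu[1], s[1]) + (1 - w) * dnorm(x, mu[2], s[2])))
  }
  trace <- loglik_of(w, mu, s)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E step
    d1 <- w * dnorm(x, mu[1], s[1])
    d2 <- (1 - w) * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    # M step
    n1 <- sum(g); n2 <- length(x) - n1
    if (n1 < 1e-10 || n2 < 1e-10) {
      stop("degenerate fit: a component vanished; consider fewer components",
           call. = FALSE)
    }
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    s <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                sum((1 - g) * (x - mu[2])^2) / n2))
    if (any(s < 1e-8)) {
      stop("degenerate fit: component variance collapsed; consider fewer components",
           call. = FALSE)
    }
    w <- n1 / length(x)
    ll <- loglik_of(w, mu, s)
    trace <- c(trace, ll)
    if (abs(ll - trace[length(trace) - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); s <- rev(s); w <- 1 - w
  }
  structure(list(mean_short = mu[1], mean_long = mu[2],
                 sd_short = s[1], sd_long = s[2], weight_short = w,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = iter, converged = converged, n = length(x)),
            class = "length_mixture")
}

#' @export
print.length_mixture <- function(x, ...) {
  cat("Two-Gaussian cell-length mixture (EM)\n")
  cat(sprintf("  short: mean %.2f um, sd %.2f, weight %.3f\n",
              x$mean_short, x$sd_short, x$weight_short))
  cat(sprintf("  long : mean %.2f um, sd %.2f, weight %.3f\n",
              x$mean_long, x$sd_long, 1 - x$weight_short))
  cat(sprintf("  loglik %.3f after %d iterations (%s)\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Posterior probability of the short (meristem) component
#'
#' Bayes posterior of membership in the short-length Gaussian for one or
#' more cell lengths, computed in log space for numerical stability.
#'
#' @param fit A [fit_length_mixture()] result.
#' @param length Numeric vector of lengths (um).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
posterior_short <- function(fit, length) {
  stopifnot(inherits(fit, "length_mixture"))
  l1 <- log(fit$weight_short) +
    dnorm(length, fit$mean_short, fit$sd_short, log = TRUE)
  l2 <- log(1 - fit$weight_short) +
    dnorm(length, fit$mean_long, fit$sd_long, log = TRUE)
  z <- pmin(pmax(l2 - l1, -700), 700)  # keep the posterior inside (0, 1]
  1 / (1 + exp(z))
}

#' Classify cells into meristem and elongation zone
#'
#' Fits a two-Gaussian length mixture per tissue x condition stratum and
#' labels cells whose posterior probability of the short component exceeds
#' `threshold` (strictly) as meristem cells.
#'
#' @param cells Data frame with at least `tissue`, `treatment` and `length`
#'   columns (e.g. from [generate_geometry_table()]).
#' @param threshold Posterior probability cut; cells with
#'   `posterior_short > threshold` are meristem.
#' @param ... Passed to [fit_length_mixture()].
#' @return `cells` with added columns `posterior_short` and `zone`
#'   (`"meristem"`/`"elongation"`, `NA` for skipped strata). Attributes:
#'   `fits` (named list of per-stratum mixture fits) and `zone_counts`
#'   (data frame of per-stratum meristem/elongation counts).
#' @export
classify_meristem <- function(cells, threshold = 0.8, ...) {
  need <- c("tissue", "treatment", "length")
  if (!all(need %in% names(cells))) {
    stop("cells must have tissue, treatment and length columns",
         call. = FALSE)
  }
  strata <- interaction(cells$tissue, cells$treatment, drop = TRUE,
                        sep = ":")
  post <- rep(NA_real_, nrow(cells))
  fits <- list()
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 10) {
      warning(sprintf("stratum %s has < 10 cells; skipped", s),
              call. = FALSE)
      next
    }
    fit <- fit_length_mixture(cells$length[idx], ...)
    fits[[s]] <- fit
    post[idx] <- posterior_short(fit, cells$length[idx])
  }
  zone <- ifelse(is.na(post), NA_character_,
                 ifelse(post > threshold, "meristem", "elongation"))
  cells$posterior_short <- post
  cells$zone <- zone
  counts <- as.data.frame(table(stratum = strata, zone = zone))
  attr(cells, "fits") <- fits
  attr(cells, "zone_counts") <- counts
  cells
}
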