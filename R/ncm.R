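#' Fit the Sloan neutral community model
#'
#' Fits the neutral prediction of occurrence frequency from metacommunity
#' relative abundance. For a species with mean relative abundance p across
#' the local communities, the neutral expectation of the fraction of
#' communities in which it is detected is
#' \deqn{F(p) = 1 - \mathrm{BetaCDF}(d;\; Nm\,p,\; Nm(1-p))}
#' where N is the local community size (taken as the mean per-sample total),
#' m the migration probability, and d = 1/N the detection limit
#' (\code{detection = "threshold"}, the classical continuous
#' approximation). The default \code{detection = "betabinomial"} replaces
#' the threshold approximation by the exact probability that a species is
#' observed at least once when N individuals are drawn from a community
#' whose relative abundance follows the same beta law:
#' \deqn{F(p) = 1 - B(Nmp,\; Nm(1-p) + N) / B(Nmp,\; Nm(1-p))}
#' which removes the finite-size bias of the threshold form (the threshold
#' approximation systematically overestimates m on count data of this
#' kind). m is estimated by least squares on the observed frequencies
#' (coarse grid search refined by Levenberg-Marquardt), and overall fit
#' quality is R^2 = 1 - SS_res/SS_tot. R^2 may be negative and is reported
#' as is.
#'
#' A 95\% envelope around the fitted curve (Wilson score interval of the
#' predicted frequency at the realized number of samples) partitions species
#' into below / within / above the neutral expectation; a large fraction
#' within indicates assembly dominated by stochastic dispersal, species
#' above are detected more often than neutrality predicts (e.g. habitat
#' generalists), species below less often (e.g. dispersal-limited
#' specialists).
#'
#' @param ab an \code{abundance_table}
#' @param scope optional metadata filter as in \code{\link{subset_samples}}
#' @param detection \code{"betabinomial"} (exact finite-sample detection,
#'   default) or \code{"threshold"} (classical beta CDF at d = 1/N)
#' @return object of class \code{ncm_fit} with elements \code{m},
#'   \code{m_ci} (asymptotic 95\% interval), \code{N}, \code{Nm},
#'   \code{R2}, \code{n_samples}, \code{n_species}, \code{data} (per-species
#'   p, observed and predicted frequency, envelope, partition),
#'   \code{fraction_within}, \code{fraction_below}, \code{fraction_above}
#' @export
fit_ncm <- function(ab, scope = NULL,
                    detection = c("betabinomial", "threshold")) {
  detection <- match.arg(detection)
  sub <- subset_samples(ab, scope)
  m0 <- sub$counts
  if (nrow(m0) < 5) stop("NCM fit needs at least 5 samples")
  totals <- rowSums(m0)
  if (any(totals == 0)) stop("zero-total sample(s) in scope")
  rel <- m0 / totals
  p <- colMeans(rel)
  freq <- colMeans(m0 > 0)
  keep <- p > 0
  p <- p[keep]; freq <- freq[keep]
  if (length(p) < 10) stop("NCM fit needs at least 10 species with records")

  N <- mean(totals)
  d <- 1 / N
  nsamp <- nrow(m0)

  pred_fun <- function(m, pp) {
    a <- N * m * pp
    b <- N * m * (1 - pp)
    if (detection == "threshold") {
      stats::pbeta(d, a, b, lower.tail = FALSE)
    } else {
      1 - exp(lbeta(a, b + N) - lbeta(a, b))
    }
  }
  sse <- function(m) sum((freq - pred_fun(m, p))^2)

  grid <- exp(seq(log(1e-4), log(1), length.out = 120))
  m_grid <- grid[which.min(vapply(grid, sse, 0))]

  m_hat <- m_grid
  m_ci <- c(NA_real_, NA_real_)
  fit <- tryCatch(
    minpack.lm::nlsLM(freq ~ pred_fun(m, p),
                      start = list(m = m_grid),
                      lower = 1e-6, upper = 1,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    m_hat <- unname(stats::coef(fit)["m"])
    se <- tryCatch(summary(fit)$coefficients["m", "Std. Error"],
                   error = function(e) NA_real_)
    if (is.finite(se)) {
      m_ci <- c(max(m_hat - 1.96 * se, 0), min(m_hat + 1.96 * se, 1))
    }
  } else {
    warning("least-squares refinement failed; grid estimate reported")
  }

  pred <- pred_fun(m_hat, p)
  ss_res <- sum((freq - pred)^2)
  ss_tot <- sum((freq - mean(freq))^2)
  degenerate <- ss_tot == 0
  if (degenerate) warning("all species share one frequency: R^2 undefined")
  r2 <- if (degenerate) NA_real_ else 1 - ss_res / ss_tot

  # Wilson score interval around the predicted frequency at nsamp samples
  z <- stats::qnorm(0.975)
  denom <- 1 + z^2 / nsamp
  centre <- (pred + z^2 / (2 * nsamp)) / denom
  half <- z * sqrt(pred * (1 - pred) / nsamp + z^2 / (4 * nsamp^2)) / denom
  lower <- pmax(centre - half, 0)
  upper <- pmin(centre + half, 1)
  part <- ifelse(freq < lower, "below", ifelse(freq > upper, "above",
                                               "within"))

  dat <- data.frame(species = names(p), p = p, freq = freq, pred = pred,
                    lower = lower, upper = upper, partition = part,
                    stringsAsFactors = FALSE, row.names = NULL)
  dat <- dat[order(dat$p), , drop = FALSE]

  structure(list(
    m = m_hat, m_ci = m_ci, N = N, Nm = N * m_hat, R2 = r2,
    detection = detection,
    n_samples = nsamp, n_species = length(p), data = dat,
    fraction_within = mean(part == "within"),
    fraction_below = mean(part == "below"),
    fraction_above = mean(part == "above"),
    degenerate = degenerate,
    scope = if (is.null(scope)) "all" else
      paste(names(scope), vapply(scope, paste, "", collapse = "|"),
            sep = "=", collapse = "; ")
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  scope: %s (%d samples, %d species)\n",
              x$scope, x$n_samples, x$n_species))
  cat(sprintf("  m = %.4f  Nm = %.1f  N = %.1f  R2 = %s\n",
              x$m, x$Nm, x$N,
              if (is.na(x$R2)) "NA" else sprintf("%.3f", x$R2)))
  cat(sprintf("  species within / below / above envelope: %.1f%% / %.1f%% / %.1f%%\n",
              100 * x$fraction_within, 100 * x$fraction_below,
              100 * x$fraction_above))
  invisible(x)
}

#' @export
summary.ncm_fit <- function(object, ...) {
  print(object)
  if (all(is.finite(object$m_ci))) {
    cat(sprintf("  95%% CI for m: [%.4f, %.4f]\n",
                object$m_ci[1], object$m_ci[2]))
  }
  invisible(object)
}

#' @export
coef.ncm_fit <- function(object, ...) {
  c(m = object$m, Nm = object$Nm, N = object$N, R2 = object$R2)
}

#' Predicted neutral occurrence frequency
#'
#' @param object an \code{ncm_fit}
#' @param p optional vector of mean relative abundances; defaults to the
#'   fitted species
#' @param ... ignored
#' @return predicted frequencies in [0, 1]
#' @export
predict.ncm_fit <- function(object, p = NULL, ...) {
  p <- p %||% object$data$p
  a <- object$Nm * p
  b <- object$Nm * (1 - p)
  if (identical(object$detection, "threshold")) {
    stats::pbeta(1 / object$N, a, b, lower.tail = FALSE)
  } else {
    1 - exp(lbeta(a, b + object$N) - lbeta(a, b))
  }
}

#' @export
residuals.ncm_fit <- function(object, ...) {
  object$data$freq - object$data$pred
}

#' Plot a neutral-model fit
#'
#' Occurrence frequency against log10 mean relative abundance with the
#' fitted neutral curve and its 95\% envelope; points coloured by their
#' position relative to the envelope.
#'
#' @param x an \code{ncm_fit}
#' @param ... passed to \code{plot}
#' @export
plot.ncm_fit <- function(x, ...) {
  dat <- x$data
  cols <- c(within = "grey30", above = "#2166ac", below = "#b2182b")
  plot(log10(dat$p), dat$freq, pch = 19, cex = 0.7,
       col = cols[dat$partition],
       xlab = "log10 mean relative abundance",
       ylab = "occurrence frequency", ylim = c(0, 1), ...)
  ord <- order(dat$p)
  graphics::lines(log10(dat$p[ord]), dat$pred[ord], lwd = 2)
  graphics::lines(log10(dat$p[ord]), dat$lower[ord], lty = 2)
  graphics::lines(log10(dat$p[ord]), dat$upper[ord], lty = 2)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("m = %.3f, Nm = %.0f, R2 = %.2f",
                                    x$m, x$Nm, x$R2))
  invisible(x)
}

#' Tabulate and rank neutral-model fits across scopes
#'
#' @param fits named list of \code{ncm_fit} objects (>= 2)
#' @return data.frame sorted by decreasing R2 (stable for ties) with
#'   columns \code{scope}, \code{m}, \code{Nm}, \code{R2},
#'   \code{fraction_within}
#' @export
compare_scopes <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits to compare")
  nm <- names(fits) %||% vapply(fits, function(f) f$scope, "")
  out <- data.frame(
    scope = nm,
    m = vapply(fits, function(f) f$m, 0),
    Nm = vapply(fits, function(f) f$Nm, 0),
    R2 = vapply(fits, function(f) f$R2, 0),
    fraction_within = vapply(fits, function(f) f$fraction_within, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$R2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
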