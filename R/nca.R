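# Non-compartmental analysis: linear-up/log-down AUC, automatic terminal
# slope selection, extrapolation to infinity.

#' Non-compartmental analysis of a concentration-time profile
#'
#' AUC by the linear-up/log-down trapezoid; terminal slope by log-linear
#' regression over the best (adjusted R-squared) of the last 3 to 8 positive
#' observations excluding Cmax; `AUC0-inf = AUC0-t + Clast / lambda_z`.
#'
#' @param profile A `pbpk_profile`, `synth_profile`, or any list/data frame
#'   with `time` (h) and `conc` fields.
#' @param subject Optional subject identifier carried into the result.
#' @return Object of class `pk_metrics`: `cmax`, `tmax`, `auc_0_t`,
#'   `auc_0_inf` (NA when no valid terminal phase), `lambda_z`, `t_half`,
#'   `extrap_pct`, `flags` (character).
#' @export
nca <- function(profile, subject = NA) {
  tt <- profile$time
  cc <- profile$conc
  ok <- is.finite(tt) & is.finite(cc)
  tt <- tt[ok]; cc <- cc[ok]
  o <- order(tt)
  tt <- tt[o]; cc <- cc[o]
  flags <- character()
  if (!length(cc) || all(cc <= 0)) {
    return(structure(list(subject = subject, cmax = 0, tmax = NA_real_,
                          auc_0_t = 0, auc_0_inf = NA_real_,
                          lambda_z = NA_real_, t_half = NA_real_,
                          extrap_pct = NA_real_, flags = "all-zero profile"),
                     class = "pk_metrics"))
  }
  cmax <- max(cc)
  imax <- which.max(cc)
  tmax <- tt[imax]

  # linear-up/log-down trapezoid
  dt <- diff(tt)
  c1 <- cc[-length(cc)]; c2 <- cc[-1]
  seg <- (c1 + c2) / 2
  logdown <- c2 < c1 & c2 > 0
  seg[logdown] <- (c1[logdown] - c2[logdown]) / log(c1[logdown] / c2[logdown])
  auc_t <- sum(seg * dt)

  # terminal slope: best adjusted R^2 over last 3..8 positive points after Cmax
  idx <- which(cc > 0 & seq_along(cc) > imax)
  lambda <- NA_real_
  if (length(idx) >= 3) {
    best <- -Inf
    for (k in 3:min(8, length(idx))) {
      pts <- utils::tail(idx, k)
      fit <- stats::lm.fit(cbind(1, tt[pts]), log(cc[pts]))
      sl <- fit$coefficients[[2]]
      r2 <- 1 - sum(fit$residuals^2) / sum((log(cc[pts]) - mean(log(cc[pts])))^2)
      adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
      if (sl < 0 && adj > best) {
        best <- adj
        lambda <- -sl
      }
    }
  }
  if (!is.finite(lambda) || lambda <= 0) {
    flags <- c(flags, "no valid terminal phase; AUC0-inf not estimated")
    auc_inf <- NA_real_
    extrap <- NA_real_
  } else {
    clast <- cc[max(which(cc > 0))]
    auc_inf <- auc_t + clast / lambda
    extrap <- 100 * (clast / lambda) / auc_inf
    if (extrap > 20) flags <- c(flags, "extrapolated fraction > 20%")
  }
  structure(list(subject = subject, cmax = cmax, tmax = tmax,
                 auc_0_t = auc_t, auc_0_inf = auc_inf, lambda_z = lambda,
                 t_half = if (is.finite(lambda)) log(2) / lambda else NA_real_,
                 extrap_pct = extrap, flags = flags),
            class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("PK metrics: Cmax %.4g at %.3g h; AUC0-t %.5g; AUC0-inf %s",
              x$cmax, x$tmax, x$auc_0_t,
              if (is.finite(x$auc_0_inf)) sprintf("%.5g", x$auc_0_inf) else "NA"))
  if (is.finite(x$lambda_z))
    cat(sprintf("; lambda_z %.4g 1/h (%.3g%% extrapolated)", x$lambda_z,
                x$extrap_pct))
  cat("\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Geometric mean ratio with confidence interval
#'
#' Paired (within-subject) geometric mean ratio of an exposure metric:
#' `exp(mean(log(test / ref)))` with a t-based confidence interval on the log
#' scale.
#'
#' @param test,ref Paired numeric vectors of per-subject metrics.
#' @param alpha Two-sided error rate (default 0.10 for a 90% CI).
#' @return Named numeric vector `gmr`, `lo`, `hi`, `n`.
#' @export
gmr <- function(test, ref, alpha = 0.10) {
  if (length(test) != length(ref)) stop("unpaired metric vectors")
  ok <- is.finite(test) & is.finite(ref) & test > 0 & ref > 0
  lr <- log(test[ok] / ref[ok])
  n <- length(lr)
  if (n < 1) stop("no usable pairs")
  m <- mean(lr)
  half <- if (n > 1) stats::qt(1 - alpha / 2, n - 1) * stats::sd(lr) / sqrt(n) else 0
  c(gmr = exp(m), lo = exp(m - half), hi = exp(m + half), n = n)
}

geomean <- function(x) exp(mean(log(x[is.finite(x) & x > 0])))
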