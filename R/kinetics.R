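#' Fit a one-site binding hyperbola (Michaelis-Menten) to uptake data
#'
#' Least-squares fit of \code{v = Vmax * S / (KM + S)} by
#' Levenberg-Marquardt (via \code{minpack.lm::nlsLM}), initialized at
#' \code{Vmax0 = max(rate)} and \code{KM0} = the concentration whose rate is
#' nearest half-max.  Standard errors are asymptotic (from the Jacobian);
#' 95\% confidence limits use the t distribution with \code{n - 2} degrees
#' of freedom.  When the fitted \code{KM} exceeds the largest tested
#' concentration the fit is flagged as unsaturated: the data do not
#' constrain \code{KM} from above and it should be read as a lower bound.
#'
#' @param data data.frame with columns \code{concentration} and \code{rate}
#'   (replicates allowed as repeated concentrations; an optional
#'   \code{replicate} column is used by \code{\link{compare_fits}}).
#' @param conc_units,rate_units unit labels carried into the result.
#' @param label dataset label.
#' @return an object of class \code{mm_fit} with components \code{KM},
#'   \code{Vmax}, \code{se_KM}, \code{se_Vmax}, \code{ci95_KM},
#'   \code{ci95_Vmax}, \code{converged}, \code{saturation_flag},
#'   \code{rss}, \code{df}, \code{data}, plus \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{residuals} and \code{plot} methods.
#' @export
fit_michaelis_menten <- function(data, conc_units = "mM",
                                 rate_units = "au", label = "") {
  stopifnot(all(c("concentration", "rate") %in% names(data)))
  s <- data$concentration; v <- data$rate
  if (any(s < 0)) stop("concentrations must be non-negative")
  if (length(unique(s)) < 4L)
    stop("insufficient data: need >= 4 distinct concentrations")
  # fit on rates scaled to ~1 so the optimum is exactly scale-equivariant;
  # Vmax and its uncertainty are scaled back afterwards
  vscale <- max(abs(v))
  if (vscale == 0) vscale <- 1
  v_ <- v / vscale
  vmax0 <- max(v_)
  km0 <- s[which.min(abs(v_ - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(s[s > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ Vmax * concentration / (KM + concentration),
                      data = data.frame(concentration = s, rate = v_),
                      start = list(Vmax = vmax0, KM = km0),
                      lower = c(Vmax = 0, KM = 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  n <- length(v); dfree <- n - 2L
  if (is.null(fit)) {
    out <- list(KM = NA_real_, Vmax = NA_real_, se_KM = NA_real_,
                se_Vmax = NA_real_, ci95_KM = c(NA_real_, NA_real_),
                ci95_Vmax = c(NA_real_, NA_real_), converged = FALSE,
                saturation_flag = NA, rss = NA_real_, df = dfree,
                conc_units = conc_units, rate_units = rate_units,
                label = label, data = data)
    class(out) <- "mm_fit"
    return(out)
  }
  co <- stats::coef(fit)
  ## Gauss-Newton polish with the analytic Jacobian: converges the
  ## flat-valley tail of the optimum to machine precision
  p <- c(co[["Vmax"]], co[["KM"]])
  rss_of <- function(p) sum((v_ - p[1] * s / (p[2] + s))^2)
  cur <- rss_of(p)
  for (it in 1:50) {
    fpred <- p[1] * s / (p[2] + s)
    J <- cbind(s / (p[2] + s), -p[1] * s / (p[2] + s)^2)
    delta <- tryCatch(solve(crossprod(J), crossprod(J, v_ - fpred)),
                      error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      cand <- p + step * as.vector(delta)
      if (cand[2] > 0 && rss_of(cand) <= cur + 1e-300) break
      step <- step / 2
      if (step < 1e-8) { cand <- p; break }
    }
    moved <- sum(abs(cand - p) / pmax(abs(p), 1e-12))
    p <- cand; cur <- rss_of(p)
    if (moved < 1e-15) break
  }
  km <- p[2]; vmax <- vscale * p[1]
  fpred <- p[1] * s / (p[2] + s)
  J <- cbind(s / (p[2] + s), -p[1] * s / (p[2] + s)^2)
  sigma2 <- sum((v_ - fpred)^2) / dfree
  covm <- tryCatch(sigma2 * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, 2, 2))
  se_vmax <- vscale * sqrt(covm[1, 1])
  se_km <- sqrt(covm[2, 2])
  tq <- stats::qt(0.975, dfree)
  out <- list(
    KM = km, Vmax = vmax, se_KM = se_km, se_Vmax = se_vmax,
    ci95_KM = c(km - tq * se_km, km + tq * se_km),
    ci95_Vmax = c(vmax - tq * se_vmax, vmax + tq * se_vmax),
    converged = fit$convInfo$isConv %||% TRUE,
    saturation_flag = km > max(s),
    rss = vscale^2 * cur, df = dfree,
    conc_units = conc_units, rate_units = rate_units, label = label,
    data = data, fit = fit
  )
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("One-site hyperbola fit",
      if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  cat(sprintf("  KM   = %.4g %s (SE %.3g, 95%% CI [%.4g ; %.4g])\n",
              x$KM, x$conc_units, x$se_KM, x$ci95_KM[1], x$ci95_KM[2]))
  cat(sprintf("  Vmax = %.4g %s (SE %.3g, 95%% CI [%.4g ; %.4g])\n",
              x$Vmax, x$rate_units, x$se_Vmax, x$ci95_Vmax[1],
              x$ci95_Vmax[2]))
  if (isTRUE(x$saturation_flag))
    cat("  note: KM exceeds the largest tested concentration;",
        "uptake did not saturate and KM is a lower bound\n")
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(KM = object$KM, Vmax = object$Vmax)

#' @export
summary.mm_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  RSS = %.4g on %d df, n = %d points\n", object$rss,
              object$df, nrow(object$data)))
  invisible(object)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$concentration
       else newdata$concentration
  object$Vmax * s / (object$KM + s)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$data$rate - predict(object)
}

#' @export
plot.mm_fit <- function(x, ...) {
  s <- x$data$concentration; v <- x$data$rate
  plot(s, v, xlab = paste0("[S] (", x$conc_units, ")"),
       ylab = paste0("rate (", x$rate_units, ")"),
       main = if (nzchar(x$label)) x$label else "Michaelis-Menten fit", ...)
  sg <- seq(0, max(s), length.out = 200)
  graphics::lines(sg, x$Vmax * sg / (x$KM + sg))
  graphics::abline(v = x$KM, lty = 3)
  invisible(x)
}

#' Compare two Michaelis-Menten fits (e.g. wild type vs mutant)
#'
#' Reports the KM fold change b/a and, when both datasets carry a
#' \code{replicate} column with at least two replicates each, an unpaired
#' two-sample t-test on per-replicate KM estimates.  When either fit is
#' saturation-flagged the fold change is reported as a lower bound
#' (\code{bound = ">="}), mirroring the convention of reporting "at least
#' n-fold" when one arm never saturates.
#'
#' @param a,b \code{mm_fit} objects (a = reference, b = comparison).
#' @param data_a,data_b the datasets behind the fits; default the data
#'   stored in the fit objects.
#' @return list with \code{fold_change_KM}, \code{bound} ("=" or ">="),
#'   \code{t_test} (htest or NULL), \code{per_replicate_KM_a/b}.
#' @export
compare_fits <- function(a, b, data_a = a$data, data_b = b$data) {
  if (a$conc_units != b$conc_units)
    stop("unit error: fits use different concentration units (",
         a$conc_units, " vs ", b$conc_units, ")")
  fold <- b$KM / a$KM
  bound <- if (isTRUE(a$saturation_flag) || isTRUE(b$saturation_flag))
    ">=" else "="
  per_rep_km <- function(d) {
    if (!("replicate" %in% names(d))) return(NULL)
    reps <- split(d, d$replicate)
    if (length(reps) < 2L) return(NULL)
    vapply(reps, function(r)
      tryCatch(fit_michaelis_menten(r)$KM, error = function(e) NA_real_),
      numeric(1))
  }
  ka <- per_rep_km(data_a); kb <- per_rep_km(data_b)
  tt <- NULL
  if (!is.null(ka) && !is.null(kb) &&
      sum(!is.na(ka)) >= 2L && sum(!is.na(kb)) >= 2L)
    tt <- stats::t.test(kb[!is.na(kb)], ka[!is.na(ka)], var.equal = FALSE)
  list(fold_change_KM = fold, bound = bound, t_test = tt,
       per_replicate_KM_a = ka, per_replicate_KM_b = kb)
}

#' Read uptake kinetics data from CSV
#'
#' Expected columns: \code{label}, \code{concentration}, \code{rate} and
#' optionally \code{replicate}.
#'
#' @param path CSV path.
#' @return named list of data.frames, one per label.
#' @export
read_kinetics_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("concentration", "rate") %in% names(df)))
  if (!("label" %in% names(df))) df$label <- "dataset"
  split(df, df$label)
}
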