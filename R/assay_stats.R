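#' Fit the Hill equation to dose-response data
#'
#' Least-squares fit of the three-parameter Hill model
#' \deqn{y = A_1 \, c^{n_H} / (EC_{50}^{n_H} + c^{n_H})}
#' to background-subtracted optical densities. The zero-baseline form is
#' appropriate when blank wells have been subtracted before fitting. The fit
#' is multi-start: `A1` starts at the largest per-concentration mean, `EC50`
#' at the concentration whose mean response is nearest half-maximum, and
#' `nH` at 0.5, 1 and 2; the converged start with the smallest residual sum
#' of squares wins. Standard errors come from the fit covariance. The fit is
#' flagged non-converged when the optimizer fails for every start, when the
#' response shows no dose dependence, or when the fitted `EC50` leaves the
#' tested concentration range by more than 10-fold.
#'
#' @param x A formula such as `od ~ concentration_M` (with `data`), a
#'   data.frame with columns `concentration_M` and `od`, or a numeric vector
#'   of concentrations (molar, > 0) with responses in `od`.
#' @param data data.frame for the formula interface.
#' @param od Numeric responses for the default interface.
#' @param ... Unused.
#' @return An object of class `hill_fit` with `coefficients`
#'   (`A1`, `EC50`, `nH`), `se`, `residual_ss`, `converged`, `diagnostic`,
#'   `fitted.values`, `residuals`, `data`, and methods for `print`,
#'   `summary`, `coef`, `vcov`, `predict`, `residuals`, `fitted`, `plot`
#'   and `simulate`.
#' @examples
#' conc <- 10^seq(-10, -6, length.out = 8)
#' od <- 2 * conc / (5e-8 + conc)
#' fit <- fit_hill(conc, od)
#' coef(fit)
#' @export
fit_hill <- function(x, ...) UseMethod("fit_hill")

#' @rdname fit_hill
#' @export
fit_hill.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  fit_hill.default(mf[[2]], mf[[1]], ...)
}

#' @rdname fit_hill
#' @export
fit_hill.data.frame <- function(x, ...) {
  if (!all(c("concentration_M", "od") %in% names(x)))
    stop("data.frame must have columns 'concentration_M' and 'od'")
  fit_hill.default(x$concentration_M, x$od, ...)
}

#' @rdname fit_hill
#' @export
fit_hill.default <- function(x, od, ...) {
  conc <- as.numeric(x)
  od <- as.numeric(od)
  if (length(conc) != length(od)) stop("concentration and od lengths differ")
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations")
  if (all(od == 0)) stop("all responses are zero")
  dat <- data.frame(conc = conc, od = od)
  means <- tapply(od, conc, mean)
  cu <- as.numeric(names(means))

  new_fit <- function(converged, diagnostic, coefs = c(A1 = NA_real_,
                      EC50 = NA_real_, nH = NA_real_), se = coefs * NA,
                      vc = NULL, rss = NA_real_, fitted = rep(NA_real_,
                      nrow(dat)), sigma = NA_real_) {
    structure(list(coefficients = coefs, se = se, vcov = vc,
                   residual_ss = rss, converged = converged,
                   diagnostic = diagnostic, fitted.values = fitted,
                   residuals = dat$od - fitted, sigma = sigma, data = dat,
                   call = sys.call(-1)),
              class = "hill_fit")
  }

  if (diff(range(means)) <= .Machine$double.eps^0.5 * max(abs(means), 1))
    return(new_fit(FALSE, "no dose dependence"))

  a1_0 <- max(means)
  ec_0 <- cu[which.min(abs(means - a1_0 / 2))]
  best <- NULL
  for (nh0 in c(0.5, 1, 2)) {
    f <- tryCatch(
      minpack.lm::nlsLM(od ~ A1 * conc^nH / (EC50^nH + conc^nH), data = dat,
                        start = list(A1 = a1_0, EC50 = ec_0, nH = nh0),
                        lower = c(1e-12, 1e-15, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = f, rss = rss)
  }
  if (is.null(best))
    return(new_fit(FALSE, "optimizer failed for all starts"))
  f <- best$fit
  cf <- stats::coef(f)[c("A1", "EC50", "nH")]
  sm <- summary(f)
  se <- sm$coefficients[c("A1", "EC50", "nH"), "Std. Error"]
  fitted <- as.numeric(stats::fitted(f))
  out <- new_fit(TRUE, "ok", cf, se, stats::vcov(f), best$rss, fitted,
                 sm$sigma)
  if (cf["EC50"] > 10 * max(conc) || cf["EC50"] < min(conc) / 10) {
    out$converged <- FALSE
    out$diagnostic <- sprintf(
      "EC50 (%.3g M) outside tested range [%.3g, %.3g] by > 10-fold",
      cf["EC50"], min(conc), max(conc))
  }
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit: y = A1 * c^nH / (EC50^nH + c^nH)\n")
  if (x$converged) {
    cat(sprintf("  A1   = %.4g +/- %.3g\n", x$coefficients["A1"], x$se["A1"]))
    cat(sprintf("  EC50 = %.4g M (%.4g nM) +/- %.3g nM\n",
                x$coefficients["EC50"], x$coefficients["EC50"] * 1e9,
                x$se["EC50"] * 1e9))
    cat(sprintf("  nH   = %.4g +/- %.3g\n", x$coefficients["nH"], x$se["nH"]))
    cat(sprintf("  residual SS = %.4g on %d points\n", x$residual_ss,
                nrow(x$data)))
  } else {
    cat("  not converged:", x$diagnostic, "\n")
  }
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(coefficients = tab, converged = object$converged,
                 diagnostic = object$diagnostic,
                 residual_ss = object$residual_ss, sigma = object$sigma,
                 n = nrow(object$data)),
            class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat("Three-parameter Hill fit (", x$n, " observations)\n", sep = "")
  if (!x$converged) cat("NOT converged:", x$diagnostic, "\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("residual SS %.4g, sigma %.4g\n", x$residual_ss, x$sigma))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
vcov.hill_fit <- function(object, ...) object$vcov

#' @export
fitted.hill_fit <- function(object, ...) object$fitted.values

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.data.frame(newdata)) {
            nm <- intersect(c("conc", "concentration_M"), names(newdata))[1]
            newdata[[nm]]
          } else as.numeric(newdata)
  cf <- object$coefficients
  unname(cf["A1"] * conc^cf["nH"] / (cf["EC50"]^cf["nH"] + conc^cf["nH"]))
}

#' @export
plot.hill_fit <- function(x, ...) {
  dat <- x$data
  graphics::plot(dat$conc, dat$od, log = "x", xlab = "concentration (M)",
                 ylab = "O.D.", ...)
  if (x$converged) {
    cc <- 10^seq(log10(min(dat$conc)), log10(max(dat$conc)), length.out = 200)
    graphics::lines(cc, predict(x, cc))
  }
  invisible(x)
}

#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0,
                                                  object$sigma)))
}

## qPCR normalization ---------------------------------------------------------

#' Relative expression by dual-housekeeping delta-Ct normalization
#'
#' For each sample, target expression is computed as
#' `efficiency^-(Ct_gene - mean(Ct_hk1, Ct_hk2))`; taking the arithmetic
#' mean of the two housekeeping Ct values is equivalent to normalizing to
#' the geometric mean of their expression levels. Row order and the order of
#' the two housekeeping labels do not affect the result.
#'
#' @param table data.frame with columns `sample`, `tissue`, `gene`, `ct`
#'   (finite, positive cycles).
#' @param housekeeping Character vector of exactly two housekeeping gene
#'   ids; both must be present for every sample.
#' @param efficiency Amplification efficiency (default 2, i.e. perfect
#'   doubling per cycle).
#' @return data.frame (class `expression_table`) with one row per
#'   (sample, non-housekeeping gene): `sample`, `tissue`, `gene`, `ct`,
#'   `hk_ct_mean`, `delta_ct`, `level`. Attributes record the housekeeping
#'   genes and efficiency.
#' @examples
#' tab <- data.frame(sample = "s1", tissue = "coelomocytes",
#'                   gene = c("hk1", "hk2", "tgt"), ct = c(20, 20, 19))
#' relative_expression(tab, c("hk1", "hk2"))$level  # 2: one cycle lower
#' @export
relative_expression <- function(table, housekeeping, efficiency = 2) {
  req <- c("sample", "tissue", "gene", "ct")
  if (!all(req %in% names(table)))
    stop("table must have columns ", paste(req, collapse = ", "))
  if (length(housekeeping) != 2L)
    stop("exactly two housekeeping genes are required")
  if (any(!is.finite(table$ct)) || any(table$ct <= 0))
    stop("Ct values must be finite and positive")
  hk <- table[table$gene %in% housekeeping, ]
  hk_mean <- tapply(hk$ct, hk$sample, function(v) mean(v))
  hk_n <- tapply(hk$gene, hk$sample, function(g) length(unique(g)))
  samples <- unique(table$sample)
  missing <- samples[!(samples %in% names(hk_n)) |
                       hk_n[match(samples, names(hk_n))] < 2L]
  if (length(missing))
    stop("missing housekeeping Ct for sample(s): ",
         paste(missing, collapse = ", "))
  tgt <- table[!table$gene %in% housekeeping, , drop = FALSE]
  tgt$hk_ct_mean <- as.numeric(hk_mean[as.character(tgt$sample)])
  tgt$delta_ct <- tgt$ct - tgt$hk_ct_mean
  tgt$level <- efficiency^(-tgt$delta_ct)
  rownames(tgt) <- NULL
  structure(tgt, class = c("expression_table", "data.frame"),
            housekeeping = sort(housekeeping), efficiency = efficiency)
}

#' Per-tissue expression summary
#'
#' Mean, standard error of the mean and sample count of normalized levels
#' per (tissue, gene).
#'
#' @param x An `expression_table` from [relative_expression()].
#' @return data.frame with columns `tissue`, `gene`, `mean_level`, `sem`,
#'   `n`.
#' @export
tissue_summary <- function(x) {
  sp <- split(x$level, list(tissue = x$tissue, gene = x$gene), drop = TRUE)
  keys <- strsplit(names(sp), ".", fixed = TRUE)
  out <- data.frame(
    tissue = vapply(keys, `[`, "", 1),
    gene = vapply(keys, `[`, "", 2),
    mean_level = vapply(sp, mean, 0),
    sem = vapply(sp, function(v) stats::sd(v) / sqrt(length(v)), 0),
    n = vapply(sp, length, 0L))
  rownames(out) <- NULL
  out[order(out$gene, out$tissue), , drop = FALSE]
}
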