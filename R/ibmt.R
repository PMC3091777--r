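#' Fit per-gene contrast statistics for one comparison
#'
#' Paired mode computes per-subject differences (case minus reference) and
#' summarizes them per probe: `b` = mean difference, `s2` = sample
#' variance of the differences, `d = n_pairs - 1`, unscaled standard error
#' `u = 1/sqrt(n_pairs)`. Unpaired mode uses the group mean difference
#' with the pooled variance, `d = n1 + n2 - 2`, `u = sqrt(1/n1 + 1/n2)`.
#' The ordinary t-statistic is `b / (u * sqrt(s2))`; `a` is the mean log2
#' intensity over all samples in the comparison and drives the intensity
#' prior downstream.
#'
#' @param study An [expression_study()].
#' @param cmp A [comparison()].
#' @return Object of class `gene_stats`: a data frame with columns
#'   `probe_id`, `b`, `u`, `s2`, `d`, `a`, `sign`, with the comparison
#'   name, mode and sample size as attributes.
#' @export
fit_gene_stats <- function(study, cmp) {
  sel <- comparison_samples(study, cmp)
  x <- study$values
  if (sel$mode == "paired") {
    D <- x[, sel$case, drop = FALSE] - x[, sel$reference, drop = FALSE]
    n <- ncol(D)
    if (n - 1L < 1L)
      stop("insufficient replication in comparison '", cmp$name, "'",
           call. = FALSE)
    b <- rowMeans(D)
    s2 <- rowSums((D - b)^2) / (n - 1L)
    d <- n - 1L
    u <- 1 / sqrt(n)
    n_info <- c(pairs = n)
  } else {
    x1 <- x[, sel$case, drop = FALSE]
    x2 <- x[, sel$reference, drop = FALSE]
    n1 <- ncol(x1); n2 <- ncol(x2)
    if (n1 + n2 - 2L < 1L)
      stop("insufficient replication in comparison '", cmp$name, "'",
           call. = FALSE)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / (n1 + n2 - 2L)
    b <- m1 - m2
    d <- n1 + n2 - 2L
    u <- sqrt(1 / n1 + 1 / n2)
    n_info <- c(n1 = n1, n2 = n2)
  }
  a <- rowMeans(x[, c(sel$case, sel$reference), drop = FALSE])
  out <- data.frame(probe_id = rownames(x), b = b, u = u, s2 = s2, d = d,
                    a = a, sign = sign(b), stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, class = c("gene_stats", "data.frame"),
            comparison = cmp$name, mode = sel$mode, n = n_info)
}

#' Estimate the intensity-dependent empirical-Bayes prior
#'
#' Method-of-moments hyperparameter estimation for the hierarchical
#' variance model `s_g^2 | sigma_g^2 ~ sigma_g^2 * chisq(d_g)/d_g`,
#' `1/sigma_g^2 ~ chisq(d0)/(d0 * s0^2(a_g))`. The bias-corrected log
#' variance `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)` has
#' expectation `log(s0^2(a_g)) + digamma(d0/2) - log(d0/2)`, so a local
#' linear trend of `e_g` on mean intensity `a_g` captures the
#' intensity-dependent prior scale, and the excess spread of the residuals
#' over `trigamma(d_g/2)` identifies the prior degrees of freedom `d0`
#' through `trigamma(d0/2) = mean(r^2) * m/(m-1) - mean(trigamma(d_g/2))`,
#' solved by bisection (the trigamma function is strictly decreasing). A
#' non-positive right-hand side means the residual spread is fully
#' explained by sampling noise and `d0 = Inf` (all probes share the
#' trend variance).
#'
#' @param stats A `gene_stats` object from [fit_gene_stats()].
#' @param span Local-regression span (fraction of probes in each window)
#'   for the intensity trend.
#' @param min_probes Minimum number of probes with positive `s2` required
#'   for a stable fit.
#' @return Object of class `eb_hyper`: list with `d0`, per-probe prior
#'   variances `s0_2` (named by probe), the fitted trend `e_hat`, and
#'   `span`. Probes with `s2 == 0` are excluded from fitting but still
#'   receive a prior variance from the trend.
#' @export
estimate_eb_hyperparameters <- function(stats, span = 0.75,
                                        min_probes = 100L) {
  stopifnot(inherits(stats, "gene_stats"), span > 0, span <= 1)
  use <- stats$s2 > 0 & is.finite(stats$s2)
  m <- sum(use)
  if (m < min_probes)
    stop("need at least ", min_probes, " probes with positive residual ",
         "variance (found ", m, ")", call. = FALSE)
  d <- stats$d[use]
  e <- log(stats$s2[use]) - digamma(d / 2) + log(d / 2)
  a <- stats$a[use]
  fit <- stats::lowess(a, e, f = span, iter = 0L)
  e_hat_all <- stats::approx(fit$x, fit$y, xout = stats$a, rule = 2,
                             ties = mean)$y
  r <- e - e_hat_all[use]
  rhs <- mean(r^2) * m / (m - 1) - mean(trigamma(d / 2))
  d0 <- solve_prior_df(rhs)
  s0_2 <- if (is.infinite(d0)) exp(e_hat_all)
          else exp(e_hat_all + digamma(d0 / 2) - log(d0 / 2))
  structure(list(d0 = d0,
                 s0_2 = stats::setNames(s0_2, stats$probe_id),
                 e_hat = stats::setNames(e_hat_all, stats$probe_id),
                 span = span, n_fitted = m),
            class = "eb_hyper")
}

# Invert trigamma(d0/2) = rhs by bisection on [0.01, 1e6]; rhs <= 0 or
# below the value at the upper bound means no detectable excess spread.
solve_prior_df <- function(rhs, lower = 0.01, upper = 1e6, tol = 1e-8) {
  if (!is.finite(rhs) || rhs <= trigamma(upper / 2)) return(Inf)
  if (rhs >= trigamma(lower / 2)) return(lower)
  lo <- lower; hi <- upper
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (trigamma(mid / 2) > rhs) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.eb_hyper <- function(x, ...) {
  cat("eb_hyper: d0 =", format(x$d0), " span =", x$span,
      " median s0^2 =", format(stats::median(x$s0_2), digits = 4), "\n")
  invisible(x)
}

#' Intensity-based moderated t-test
#'
#' Shrinks each probe's residual variance toward its intensity-dependent
#' prior with weights given by the degrees of freedom:
#' `s_tilde^2 = (d0 * s0^2 + d * s2) / (d0 + d)`, then tests
#' `t = b / (u * sqrt(s_tilde^2))` against a t distribution on `d0 + d`
#' degrees of freedom (standard normal when `d0 = Inf`; the ordinary
#' t-test when `d0 = 0`). Two-sided p-values; direction is carried
#' separately in `sign`.
#'
#' @param stats A `gene_stats` object.
#' @param hyper An `eb_hyper` object (or a list with `d0` and `s0_2`).
#' @param d0 Optional override of the prior degrees of freedom (e.g. `0`
#'   to recover the classical t-test).
#' @return Object of class `moderated_result`: data frame with columns
#'   `probe_id`, `b`, `a`, `s2`, `d`, `s0_2`, `s_tilde2`, `t_mod`, `df`,
#'   `p`, `q` (Benjamini-Hochberg adjusted), `sign`, `flagged`. Probes
#'   with zero moderated variance are flagged and get `NA` p-values.
#' @export
moderated_test <- function(stats, hyper, d0 = NULL) {
  stopifnot(inherits(stats, "gene_stats"))
  if (is.null(d0)) d0 <- hyper$d0
  s0 <- hyper$s0_2[stats$probe_id]
  if (anyNA(s0)) stop("prior variance undefined for some probes", call. = FALSE)
  d <- stats$d
  s_tilde2 <-
    if (d0 == 0) stats$s2
    else if (is.infinite(d0)) s0
    else (d0 * s0 + d * stats$s2) / (d0 + d)
  df <- d0 + d
  flagged <- s_tilde2 <= 0
  t_mod <- ifelse(flagged, NA_real_, stats$b / (stats$u * sqrt(s_tilde2)))
  p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t_mod))
       else 2 * stats::pt(-abs(t_mod), df = df)
  p <- pmin(pmax(p, 1e-300), 1)
  p[flagged] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!flagged] <- bh_fdr(p[!flagged])
  out <- data.frame(probe_id = stats$probe_id, b = stats$b, a = stats$a,
                    s2 = stats$s2, d = d, s0_2 = unname(s0),
                    s_tilde2 = s_tilde2, t_mod = t_mod, df = df, p = p,
                    q = q, sign = stats$sign, flagged = flagged,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("moderated_result", "data.frame"),
            comparison = attr(stats, "comparison"), d0 = d0,
            m_tested = sum(!flagged))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, with stable ties.
#' The family size `m` defaults to the number of supplied p-values (the
#' probes tested in one comparison) but may be set larger when some tests
#' were dropped.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param m Family size (defaults to `length(p)`).
#' @return Vector of adjusted values in the input order.
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (m < length(p)) stop("family size m cannot be below length(p)",
                          call. = FALSE)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_along(p))))
  pmin(q_sorted, 1)[order(o)]
}
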