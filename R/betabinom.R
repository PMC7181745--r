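# Beta-binomial model of per-site RNA edit frequencies.
#
# At an edit site, each library contributes n reads of which k carry the
# edited (A->G / T->C) allele. k | n, p ~ Binomial(n, p) with the latent
# per-library edit frequency p ~ Beta(alpha, beta). The compound pmf is
#   f(k | n, alpha, beta) = C(n,k) B(k + alpha, n - k + beta) / B(alpha, beta).
# We work in the (mu, rho) parametrization
#   mu  = alpha / (alpha + beta)          mean edit frequency
#   rho = 1 / (alpha + beta + 1)          overdispersion, both in (0, 1),
# under which E(k) = n mu and Var(k) = n mu (1 - mu) [1 + (n - 1) rho].

.BB_EPS <- 1e-6

#' Convert (mu, rho) to beta shape parameters
#'
#' @param mu Mean edit probability, in (0, 1).
#' @param rho Overdispersion, in (0, 1). `rho = 1/(alpha + beta + 1)`, so
#'   small values approach the binomial and values near 1 a two-point
#'   mixture at 0 and 1.
#' @return List with elements `alpha` and `beta`.
#' @export
bb_shape <- function(mu, rho) {
  stopifnot(is.numeric(mu), is.numeric(rho))
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    stop("'mu' must lie strictly inside (0, 1)")
  }
  if (any(!is.finite(rho)) || any(rho <= 0) || any(rho >= 1)) {
    stop("'rho' must lie strictly inside (0, 1)")
  }
  s <- (1 - rho) / rho           # alpha + beta
  list(alpha = mu * s, beta = (1 - mu) * s)
}

#' Beta-binomial probability mass function
#'
#' Density of the number of edited reads `k` among `n` reads when the
#' per-library edit frequency is beta-distributed with mean `mu` and
#' overdispersion `rho`. Computed in log space via `lbeta()` for stability.
#'
#' @param k Number of edited-allele reads (vectorised).
#' @param n Total reads overlapping the site.
#' @param mu Mean edit probability.
#' @param rho Overdispersion in (0, 1).
#' @param log Return log density?
#' @return Probability (or log probability) of each `k`.
#' @examples
#' dbetabinom(1, 2, mu = 0.5, rho = 1/3)  # uniform beta: all outcomes 1/3
#' sum(dbetabinom(0:20, 20, 0.1, 0.05))   # normalises to 1
#' @export
dbetabinom <- function(k, n, mu, rho, log = FALSE) {
  m <- max(length(k), length(n), length(mu), length(rho))
  k <- rep_len(k, m); n <- rep_len(n, m)
  mu <- rep_len(mu, m); rho <- rep_len(rho, m)
  if (any(!is.finite(k)) || any(!is.finite(n))) stop("non-finite 'k' or 'n'")
  if (any(k < 0) || any(k > n)) stop("'k' must satisfy 0 <= k <= n")
  sh <- bb_shape(mu, rho)
  ll <- lchoose(n, k) + lbeta(k + sh$alpha, n - k + sh$beta) -
    lbeta(sh$alpha, sh$beta)
  ll[n == 0] <- 0  # single point mass at k = 0
  if (log) ll else exp(ll)
}

#' Beta-binomial moments
#'
#' @inheritParams dbetabinom
#' @return List with `mean` = `n * mu` and
#'   `variance` = `n * mu * (1 - mu) * (1 + (n - 1) * rho)`.
#' @export
bb_moments <- function(n, mu, rho) {
  bb_shape(mu, rho)  # validates
  if (any(n < 0)) stop("'n' must be >= 0")
  list(mean = n * mu, variance = n * mu * (1 - mu) * (1 + (n - 1) * rho))
}

#' Sample beta-binomial counts
#'
#' Draws a per-sample latent frequency from the beta distribution, then a
#' binomial count, matching the generative model of replicate libraries.
#'
#' @param m Number of draws.
#' @param n Total read count per draw (scalar or length `m`).
#' @inheritParams dbetabinom
#' @return Integer vector of `m` edited-read counts.
#' @export
rbetabinom <- function(m, n, mu, rho) {
  sh <- bb_shape(mu, rho)
  n <- rep_len(n, m)
  p <- stats::rbeta(m, sh$alpha, sh$beta)
  stats::rbinom(m, n, p)
}

## ---- maximum likelihood -----------------------------------------------

.logit <- function(x) log(x / (1 - x))
.expit <- function(x) 1 / (1 + exp(-x))

# Joint log-likelihood of libraries with group-specific means and shared rho.
# mu is a vector aligned with k (already expanded per library).
.bb_loglik <- function(k, n, mu, rho) {
  s <- (1 - rho) / rho
  a <- mu * s
  b <- (1 - mu) * s
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

.check_counts <- function(k, n) {
  if (length(k) != length(n)) stop("'k' and 'n' must have equal length")
  if (any(!is.finite(k)) || any(!is.finite(n))) stop("non-finite counts")
  if (any(k < 0) || any(n < 0) || any(k > n)) stop("need 0 <= k <= n")
}

# Maximise the log-likelihood over freely varying parameters on the logit
# scale. `assign` maps each library to the index of its mean parameter;
# the last parameter is always rho. Multi-start: method-of-moments plus
# fixed fallbacks; the best converged optimum wins.
.bb_fit <- function(k, n, assign, n_mu, starts) {
  covered <- n > 0
  if (!any(covered)) stop("all libraries have zero coverage at this site")
  obj <- function(theta) {
    mu <- .expit(theta[seq_len(n_mu)])[assign]
    rho <- .expit(theta[n_mu + 1L])
    -.bb_loglik(k[covered], n[covered], mu[covered], rho)
  }
  lim <- .logit(.BB_EPS)
  best <- NULL
  for (st in starts) {
    theta0 <- pmin(pmax(.logit(st), lim), -lim)
    fit <- tryCatch(
      stats::optim(theta0, obj, method = "L-BFGS-B",
                   lower = lim, upper = -lim,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
    }
  }
  if (is.null(best)) stop("beta-binomial optimisation failed for all starts")
  mu <- .expit(best$par[seq_len(n_mu)])
  rho <- .expit(best$par[n_mu + 1L])
  tol <- 10 * .BB_EPS
  list(mu = mu, rho = rho, loglik = -best$value,
       converged = best$convergence == 0L,
       boundary = any(mu <= tol) || any(mu >= 1 - tol) ||
         rho <= tol || rho >= 1 - tol)
}

# Method-of-moments start from per-library frequencies.
.bb_mom_start <- function(k, n) {
  f <- k[n > 0] / n[n > 0]
  mu <- mean(f)
  mu <- min(max(mu, 0.01), 0.99)
  v <- if (length(f) > 1) stats::var(f) else 0
  # For p ~ Beta, Var(p) = mu (1 - mu) rho
  rho <- if (mu > 0 && mu < 1) v / (mu * (1 - mu)) else 0.1
  rho <- min(max(rho, 0.005), 0.9)
  c(mu, rho)
}

#' Fit the null (shared-mean) beta-binomial model
#'
#' All libraries share one mean edit frequency `mu0` and overdispersion
#' `rho`; maximises the joint likelihood. Libraries with `n = 0` carry no
#' information and are ignored.
#'
#' @param k,n Integer vectors of edited and total read counts per library.
#' @return List with `mu0`, `rho`, `loglik`, `converged`, and `boundary`
#'   (`TRUE` when an estimate hugs the box constraint at `1e-6`).
#' @export
fit_bb_null <- function(k, n) {
  .check_counts(k, n)
  if (!any(n > 0)) stop("all libraries have zero coverage at this site")
  mom <- .bb_mom_start(k, n)
  starts <- list(c(mom[1], mom[2]), c(0.05, 0.05), c(0.5, 0.3))
  fit <- .bb_fit(k, n, assign = rep(1L, length(k)), n_mu = 1L, starts = starts)
  list(mu0 = fit$mu[1], rho = fit$rho, loglik = fit$loglik,
       converged = fit$converged, boundary = fit$boundary)
}

#' Fit the alternative (two-mean, shared-dispersion) beta-binomial model
#'
#' Group 1 and group 2 libraries get distinct means `mu1`, `mu2` with a
#' single shared `rho`, the alternative of the differential-editing test.
#'
#' @inheritParams fit_bb_null
#' @param group Factor-like vector (two levels) aligning libraries to groups.
#'   The first level (first-appearing group for a character vector) is
#'   reported as `mu1`.
#' @param null_fit Optional result of [fit_bb_null()] on the same counts;
#'   its optimum is added as a starting point, which enforces model nesting.
#' @return List with `mu1`, `mu2`, `rho`, `loglik`, `converged`, `boundary`.
#' @export
fit_bb_alt <- function(k, n, group, null_fit = NULL) {
  .check_counts(k, n)
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  if (nlevels(group) != 2L) stop("'group' must have exactly two levels")
  if (length(group) != length(k)) stop("'group' must align with counts")
  for (lv in levels(group)) {
    if (sum(n[group == lv]) == 0) {
      stop(sprintf("group '%s' has zero total coverage", lv))
    }
  }
  assign <- as.integer(group)
  g1 <- group == levels(group)[1]
  mom1 <- .bb_mom_start(k[g1], n[g1])
  mom2 <- .bb_mom_start(k[!g1], n[!g1])
  starts <- list(c(mom1[1], mom2[1], mean(c(mom1[2], mom2[2]))),
                 c(0.3, 0.02, 0.05),
                 c(0.5, 0.5, 0.3))
  if (!is.null(null_fit)) {
    starts <- c(list(c(null_fit$mu0, null_fit$mu0, null_fit$rho)), starts)
  }
  fit <- .bb_fit(k, n, assign = assign, n_mu = 2L, starts = starts)
  ll <- fit$loglik
  # The null is nested (mu1 = mu2); never report a worse alternative optimum.
  if (!is.null(null_fit) && ll < null_fit$loglik) {
    fit$mu <- c(null_fit$mu0, null_fit$mu0)
    fit$rho <- null_fit$rho
    ll <- null_fit$loglik
  }
  list(mu1 = fit$mu[1], mu2 = fit$mu[2], rho = fit$rho, loglik = ll,
       converged = fit$converged, boundary = fit$boundary)
}

#' Likelihood-ratio test for nested beta-binomial fits
#'
#' @param loglik_null,loglik_alt Maximised log-likelihoods of the nested
#'   (shared-mean) and alternative (two-mean) models.
#' @param df Degrees of freedom of the reference chi-square; the two-mean
#'   alternative adds one parameter, so the default is 1.
#' @param tol Largest tolerated negative statistic before the fits are
#'   declared inconsistent (optimiser failure).
#' @return List with `statistic` (clipped at 0) and `p_value`.
#' @export
lrt_pvalue <- function(loglik_null, loglik_alt, df = 1, tol = 1e-6) {
  stat <- 2 * (loglik_alt - loglik_null)
  if (any(stat < -tol)) {
    stop("alternative log-likelihood below null: optimiser failure")
  }
  stat <- pmax(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p-values, preserving input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA`/`NaN` is an error.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p))) stop("p-values must be finite (no NA/NaN)")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential edit frequency
#'
#' Mean per-library edit frequency (`k/n`) of the fusion group minus the
#' mean over pooled control libraries. Libraries with no coverage at the
#' site are excluded from their group's mean rather than counted as 0.
#'
#' @inheritParams fit_bb_alt
#' @param fusion Level of `group` holding the editing-competent fusion
#'   libraries; all other levels are pooled as controls.
#' @return Difference of group mean frequencies, in `[-1, 1]`; `NA` when
#'   either group has no covered library.
#' @export
diff_frequency <- function(k, n, group, fusion = unique(as.character(group))[1]) {
  .check_counts(k, n)
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  if (!fusion %in% levels(group)) stop("'fusion' is not a level of 'group'")
  covered <- n > 0
  f <- k / n
  in_fusion <- group == fusion
  if (!any(covered & in_fusion) || !any(covered & !in_fusion)) {
    return(NA_real_)
  }
  mean(f[covered & in_fusion]) - mean(f[covered & !in_fusion])
}

## ---- per-site testing over a count matrix -----------------------------

# Internal single-site differential-editing test.
.bb_test_site <- function(k, n, two_group) {
  null <- fit_bb_null(k, n)
  alt <- fit_bb_alt(k, n, two_group, null_fit = null)
  lrt <- lrt_pvalue(null$loglik, alt$loglik)
  c(mu0 = null$mu0, mu1 = alt$mu1, mu2 = alt$mu2, rho = alt$rho,
    lrt_stat = lrt$statistic, pvalue = lrt$p_value)
}

#' Differential-editing test across all sites of a count matrix
#'
#' For every site, fits the shared-mean null and the fusion-versus-control
#' alternative beta-binomial models, computes the likelihood-ratio p-value
#' (chi-square, 1 df), adjusts p-values across all tested sites by
#' Benjamini-Hochberg, and reports the differential edit frequency.
#' Control groups (e.g. catalytic-dead and empty vector) are pooled.
#'
#' @param counts A [site_counts] object.
#' @param fusion Group label of the fusion libraries (default `"fusion"`).
#' @return Data frame with one row per tested site: `site`, `contig`,
#'   `position`, `strand`, `gene`, `region`, `mu0`, `mu1` (fusion), `mu2`
#'   (control), `rho`, `lrt_stat`, `pvalue`, `fdr`, `diff_frequency`.
#'   Sites with zero fusion coverage are not tested.
#' @export
test_editing <- function(counts, fusion = "fusion") {
  stopifnot(inherits(counts, "site_counts"))
  groups <- counts$groups
  if (!fusion %in% groups) {
    stop(sprintf("no library carries the fusion group label '%s'", fusion))
  }
  two_group <- factor(ifelse(groups == fusion, "fusion", "control"),
                      levels = c("fusion", "control"))
  kmat <- counts$alt
  nmat <- counts$alt + counts$ref
  testable <- rowSums(nmat[, two_group == "fusion", drop = FALSE]) > 0 &
    rowSums(nmat[, two_group == "control", drop = FALSE]) > 0
  idx <- which(testable)
  res <- vapply(idx, function(i) {
    .bb_test_site(kmat[i, ], nmat[i, ], two_group)
  }, numeric(6))
  res <- as.data.frame(t(res))
  dfreq <- vapply(idx, function(i) {
    diff_frequency(kmat[i, ], nmat[i, ], two_group, fusion = "fusion")
  }, numeric(1))
  out <- cbind(counts$sites[idx, , drop = FALSE], res,
               fdr = bh_adjust(res$pvalue), diff_frequency = dfreq)
  rownames(out) <- NULL
  out
}

#' Select significant edit sites at an FDR threshold
#'
#' Filters a [test_editing()] (or [test_celltype()]) result for sites with
#' FDR-adjusted p strictly below the threshold. Named presets reflect the
#' experiment classes of the originating study: `"MOLM13"` 0.05,
#' `"LSC"`/`"LSK"` 0.01, `"HSPC"` 0.1.
#'
#' @param results Data frame with an `fdr` column.
#' @param fdr_threshold Numeric threshold in (0, 1], or a preset name.
#' @return The significant subset of `results`.
#' @export
call_significant_sites <- function(results, fdr_threshold = 0.05) {
  thr <- fdr_preset(fdr_threshold)
  stopifnot(is.data.frame(results), "fdr" %in% names(results))
  results[results$fdr < thr, , drop = FALSE]
}

#' Resolve an FDR threshold preset
#'
#' @param x A number in (0, 1] or one of `"MOLM13"` (0.05), `"LSC"`,
#'   `"LSK"` (0.01), `"HSPC"` (0.1).
#' @return Numeric threshold.
#' @export
fdr_preset <- function(x) {
  if (is.character(x)) {
    presets <- c(MOLM13 = 0.05, LSC = 0.01, LSK = 0.01, HSPC = 0.1)
    if (!x %in% names(presets)) {
      stop(sprintf("unknown FDR preset '%s'; use one of %s or a number",
                   x, paste(names(presets), collapse = ", ")))
    }
    return(unname(presets[x]))
  }
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0 || x > 1) {
    stop("FDR threshold must be a single number in (0, 1]")
  }
  x
}

#' One-cell-type-versus-rest differential-editing test
#'
#' Null: all cell types share one beta distribution of edit frequencies.
#' Alternative: the target cell type has its own mean while the remaining
#' cell types are pooled, with a shared overdispersion. P-values are
#' adjusted across all tested sites; the conventional significance call
#' for cell-type specificity is adjusted p < 0.1.
#'
#' @param counts A [site_counts] object whose group labels are cell types.
#' @param target Cell type of interest.
#' @return Data frame as in [test_editing()], where `mu1` is the target
#'   cell type's mean and `mu2` the pooled rest; `diff_frequency` is the
#'   target-versus-rest difference of mean per-library frequencies.
#' @export
test_celltype <- function(counts, target) {
  stopifnot(inherits(counts, "site_counts"))
  if (!target %in% counts$groups) {
    stop(sprintf("cell type '%s' has no libraries", target))
  }
  if (length(unique(counts$groups)) < 2L) {
    stop("need at least two cell types")
  }
  relab <- counts
  relab$groups <- ifelse(counts$groups == target, "fusion", "control")
  names(relab$groups) <- names(counts$groups)
  out <- test_editing(relab, fusion = "fusion")
  names(out)[names(out) == "mu1"] <- "mu_target"
  names(out)[names(out) == "mu2"] <- "mu_rest"
  out
}
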