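## Second-order SNARE-assembly kinetics: rate-law fitting, normalization
## and rank-based group comparison of rate constants.

#' Fit the integrated second-order rate law
#'
#' Least-squares fit of
#' `SC(t) = SC0 + (SCinf - SC0) * A0 k t / (A0 k t + 1)` to a
#' densitometry time course, with the initial reactant concentration
#' `A0` fixed from the experimental design (k and A0 are not separately
#' identifiable from a single curve; 3 uM is the limiting concentration
#' of the assay this package models).
#'
#' @param tc an [AssemblyTimeCourse-class] with at least 4 time points.
#' @param A0_M fixed reactant concentration (mol/L), default 3e-6.
#' @return An [AssemblyFit-class]. A fit driven to the k > 0 boundary
#'   (flat data) is flagged `converged = FALSE` with a warning.
#' @examples
#' tc <- simulateAssembly(assemblySimParams(cv_noise = 0))
#' fitAssembly(tc)
#' @export
fitAssembly <- function(tc, A0_M = 3e-6) {
  stopifnot(is(tc, "AssemblyTimeCourse"))
  if (length(tc@times_min) < 4)
    stop("need at least 4 time points to fit SC0, SCinf and k")
  if (A0_M <= 0) stop("A0_M must be positive")
  t <- tc@times_min; v <- tc@values_au
  SC0g <- min(v); SCig <- max(v)
  if (SCig - SC0g <= 1e-10 * max(abs(v), 1)) {
    warning("flat time course: rate constant driven to the k -> 0 ",
            "boundary; no kinetic information")
    return(new("AssemblyFit", SC0_au = SC0g, SCinf_au = SCig, A0_M = A0_M,
               k_M1s1 = NA_real_, residual_rms = 0, converged = FALSE))
  }
  ## k guess from the half-rise time: A0 * k * t_half = 1
  mid <- SC0g + (SCig - SC0g) / 2
  over <- which(v >= mid)
  t_half <- if (length(over) && t[over[1]] > 0) t[over[1]] else max(t) / 4
  kg <- 1 / (A0_M * max(t_half, 1e-6) * 60)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ assemblyLaw(t, SC0, SCinf, A0_M, k),
      start = list(SC0 = SC0g, SCinf = max(SCig, SC0g * 1.01 + 1e-9), k = kg),
      lower = c(SC0 = 0, SCinf = 0, k = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("assembly fit did not converge")
    return(new("AssemblyFit", SC0_au = SC0g, SCinf_au = SCig, A0_M = A0_M,
               k_M1s1 = NA_real_, residual_rms = NA_real_,
               converged = FALSE))
  }
  cf <- stats::coef(fit)
  conv <- isTRUE(fit$convInfo$isConv)
  span <- max(v) - min(v)
  at_boundary <- cf[["k"]] <= 1e-11 ||
    (cf[["SCinf"]] - cf[["SC0"]]) <= 1e-8 * max(span, abs(cf[["SC0"]]), 1e-12)
  if (at_boundary) {
    warning("rate constant driven to the k -> 0 boundary; ",
            "time course carries no kinetic information")
    conv <- FALSE
  }
  new("AssemblyFit", SC0_au = cf[["SC0"]],
      SCinf_au = max(cf[["SCinf"]], cf[["SC0"]]),
      A0_M = A0_M, k_M1s1 = cf[["k"]],
      residual_rms = sqrt(mean(stats::residuals(fit)^2)),
      converged = conv)
}

#' Normalize a time course to a reference time
#'
#' Divides all values by the value at the sample closest to `t_ref_min`
#' (within `tol_min`), so the normalized value at the reference time is
#' 1. Normalizing removes the arbitrary densitometry scale: on noiseless
#' law data the normalized curve is independent of `SCinf`.
#'
#' @param tc an [AssemblyTimeCourse-class].
#' @param t_ref_min reference time (min), default 240.
#' @param tol_min how far the nearest sample may be from `t_ref_min`.
#' @return A new, normalized [AssemblyTimeCourse-class].
#' @export
normalizeTimeCourse <- function(tc, t_ref_min = 240, tol_min = 10) {
  stopifnot(is(tc, "AssemblyTimeCourse"))
  i <- which.min(abs(tc@times_min - t_ref_min))
  if (abs(tc@times_min[i] - t_ref_min) > tol_min)
    stop(sprintf("no sample within %g min of t = %g min", tol_min, t_ref_min))
  ref <- tc@values_au[i]
  if (ref <= 0) stop("reference value must be positive")
  assemblyTimeCourse(tc@times_min, tc@values_au / ref,
                     group = tc@group, replicate = tc@replicate)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise rank comparisons on the pooled ranks, with tie correction:
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12(N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}
#' Two-sided normal p-values, optionally Bonferroni-adjusted over the
#' comparisons performed.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @param control if given, only comparisons against this group are
#'   performed; otherwise all pairs.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return A `data.frame` with one row per comparison: groups, z, raw and
#'   adjusted p, significance stars.
#' @export
dunnTest <- function(values, groups, control = NULL,
                     adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  N <- length(values)
  rk <- rank(values)
  tie <- table(rk)
  tiecorr <- sum(tie^3 - tie) / (12 * (N - 1))
  lv <- unique(groups)
  rbar <- tapply(rk, groups, mean)
  n <- tapply(rk, groups, length)
  pairs <- if (is.null(control)) {
    utils::combn(lv, 2, simplify = FALSE)
  } else {
    if (!control %in% lv) stop("control group '", control, "' not found")
    lapply(setdiff(lv, control), function(g) c(control, g))
  }
  res <- do.call(rbind, lapply(pairs, function(p) {
    z <- (rbar[[p[1]]] - rbar[[p[2]]]) /
      sqrt((N * (N + 1) / 12 - tiecorr) * (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    data.frame(group1 = p[1], group2 = p[2], z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  }))
  res$p_adjusted <- if (adjust == "bonferroni")
    pmin(res$p_value * nrow(res), 1) else res$p_value
  res$stars <- significanceStars(res$p_adjusted)
  rownames(res) <- NULL
  res
}

#' Compare SNARE assembly rates across groups
#'
#' Expresses each group's rate constant as percent of the control group
#' mean (ratio of group means, SEM by first-order error propagation),
#' tests the groups with Kruskal-Wallis, and runs Dunn's post-hoc test
#' against the control.
#'
#' @param fits a `data.frame` with columns `group` and `k` (one row per
#'   replicate fit), or a list of [AssemblyFit-class] objects with a
#'   parallel `groups` vector.
#' @param groups group labels when `fits` is a list of fits.
#' @param control control group label.
#' @param adjust p-adjustment for Dunn's test, see [dunnTest()].
#' @return A list: `relative` (group, n, mean k, percent of control,
#'   SEM), `kruskal` (the `htest`), `dunn` (pairwise table vs control).
#' @export
compareAssemblyRates <- function(fits, groups = NULL, control = "control",
                                 adjust = "bonferroni") {
  if (is.list(fits) && !is.data.frame(fits)) {
    k <- vapply(fits, rateConstant, numeric(1))
    if (is.null(groups) || length(groups) != length(k))
      stop("supply one group label per fit")
    df <- data.frame(group = as.character(groups), k = k)
  } else {
    df <- as.data.frame(fits)
    if (!all(c("group", "k") %in% names(df)))
      stop("fits must have 'group' and 'k' columns")
  }
  if (!control %in% df$group)
    stop("control group '", control, "' not present")
  if (length(unique(df$group)) < 2) stop("need at least 2 groups")
  nk <- tapply(df$k, df$group, length)
  if (any(nk < 3))
    warning("fewer than 3 replicates in some group")
  mk <- tapply(df$k, df$group, mean)
  sek <- tapply(df$k, df$group, .sem)
  c_mean <- mk[[control]]; c_se <- sek[[control]]
  rel <- 100 * mk / c_mean
  rel_se <- rel * sqrt((sek / mk)^2 + (c_se / c_mean)^2)
  rel_se[names(rel) == control] <- 100 * c_se / c_mean
  relative <- data.frame(group = names(mk), n = as.integer(nk),
                         k_mean = as.numeric(mk),
                         percent_of_control = as.numeric(rel),
                         percent_sem = as.numeric(rel_se))
  kw <- stats::kruskal.test(df$k, factor(df$group))
  dn <- dunnTest(df$k, df$group, control = control, adjust = adjust)
  list(relative = relative, kruskal = kw, dunn = dn)
}
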