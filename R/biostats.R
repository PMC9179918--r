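## Robust statistics layer: trimmed-means heteroscedastic two-way
## ANOVA with interaction (the study's omnibus test for score,
## concentration and imaging variables), a noncentral-t power /
## effect-size solver, descriptive summaries and ordinal-stage
## frequency tables for heat-map style reporting.

#' Trimmed mean, winsorized variance and effective sample size
#'
#' With `g = floor(trim * n)` observations trimmed from each tail, the
#' trimmed mean averages the central order statistics, the winsorized
#' variance is the ordinary variance of the sample with each tail
#' clamped to its innermost retained value, and the effective size is
#' `h = n - 2g`. The squared standard error of the trimmed mean
#' (Yuen) is `(n - 1) * winvar / (h * (h - 1))`. `trim = 0` reduces
#' everything to the classical mean and variance.
#'
#' @param x numeric vector, non-empty.
#' @param trim trimming fraction per tail in [0, 0.5).
#' @return List with `tmean`, `winvar`, `h`, `se2`.
#' @export
trimmedMeanStats <- function(x, trim = 0.2) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("empty input")
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
  g <- floor(trim * n)
  if (n - 2L * g < 1L) stop("trimming removes all observations")
  s <- sort(x)
  tmean <- mean(s[(g + 1L):(n - g)])
  w <- pmin(pmax(s, s[g + 1L]), s[n - g])
  winvar <- if (n > 1L) stats::var(w) else 0
  h <- n - 2L * g
  se2 <- if (h > 1L) (n - 1) * winvar / (h * (h - 1)) else NA_real_
  list(tmean = tmean, winvar = winvar, h = h, se2 = se2)
}

## Johansen-type test of C mu_t = 0 for trimmed cell means with
## heteroscedastic (Yuen) squared standard errors v and effective cell
## sizes h. Returns the Q statistic and a p-value from the adjusted
## critical value c(alpha) = q + q/(2k) * A * (1 + 3q/(k+2)),
## q = qchisq(1-alpha, k), solved for the alpha at which c(alpha) = Q.
.johansen <- function(cmat, tmeans, v, h) {
  V <- diag(v, length(v))
  Tm <- cmat %*% V %*% t(cmat)
  Ti <- tryCatch(solve(Tm), error = function(e)
    stop("degenerate design: within-cell variability is zero or the ",
         "contrast covariance is singular"))
  psi <- cmat %*% tmeans
  Q <- drop(t(psi) %*% Ti %*% psi)
  R <- V %*% t(cmat) %*% Ti %*% cmat
  A <- 0
  for (j in seq_along(h)) {
    trj <- R[j, j]
    A <- A + (trj^2 + trj^2) / (h[j] - 1)
  }
  A <- A / 2
  k <- nrow(cmat)
  crit <- function(alpha) {
    q <- stats::qchisq(1 - alpha, k)
    q + (q / (2 * k)) * A * (1 + 3 * q / (k + 2))
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  p <- if (Q <= 0) 1
  else if (crit(lo) < Q) lo
  else if (crit(hi) > Q) 1
  else stats::uniroot(function(al) crit(al) - Q, c(lo, hi),
                      tol = 1e-10)$root
  list(Q = Q, p = p)
}

.successiveDifferences <- function(k) {
  cbind(diag(k - 1L), 0) - cbind(0, diag(k - 1L))
}

#' Two-way ANOVA for trimmed means with interaction
#'
#' Heteroscedastic factorial test built from cell trimmed means and
#' winsorized variances: each cell contributes its Yuen squared
#' standard error, and main effects and the interaction are tested
#' with linear contrasts via Johansen's approximation, whose adjusted
#' critical value accounts for the small effective (trimmed) cell
#' sizes. With `trim = 0` this is the classical heteroscedastic
#' (Welch-James-Johansen) factorial ANOVA. An optional seeded
#' percentile bootstrap recomputes the p-values from null-centred cell
#' resamples.
#'
#' @param values numeric response vector.
#' @param factorA,factorB factors (or coercible) of the same length as
#'   `values`; at least two levels each, every non-empty cell with at
#'   least `h >= 2` observations after trimming.
#' @param trim trimming fraction per tail (default 0.2, the
#'   conventional robust-ANOVA choice).
#' @param method `"johansen"` (default) or `"bootstrap"`.
#' @param nboot bootstrap replicates.
#' @param seed seed for the bootstrap resamples.
#' @return A [TrimmedAnovaResult-class].
#' @examples
#' d <- makeOrdinalScoreDataset(scoreSimSpec(seed = 7))
#' trimmedTwoWayAnova(d$value, d$group, d$time_days)
#' @export
trimmedTwoWayAnova <- function(values, factorA, factorB, trim = 0.2,
                               method = c("johansen", "bootstrap"),
                               nboot = 599L, seed = 1L) {
  method <- match.arg(method)
  fA <- factor(factorA)
  fB <- factor(factorB)
  stopifnot(length(values) == length(fA), length(values) == length(fB))
  J <- nlevels(fA); K <- nlevels(fB)
  if (J < 2L || K < 2L) stop("each factor needs at least two levels")
  cells <- split(values, list(fB, fA))   # B fastest, matching contrasts
  nc <- vapply(cells, length, integer(1))
  if (any(nc == 0L))
    stop("empty cell(s): ", paste(names(cells)[nc == 0L], collapse = ", "))
  st <- lapply(cells, trimmedMeanStats, trim = trim)
  h <- vapply(st, `[[`, numeric(1), "h")
  if (any(h < 2))
    stop("cell(s) with fewer than 2 observations after trimming: ",
         paste(names(cells)[h < 2], collapse = ", "))
  tm <- vapply(st, `[[`, numeric(1), "tmean")
  v <- vapply(st, `[[`, numeric(1), "se2")
  if (all(v == 0))
    stop("degenerate design: within-cell variability is zero or the ",
         "contrast covariance is singular")

  cj <- .successiveDifferences(J)
  ck <- .successiveDifferences(K)
  oneJ <- matrix(1, 1, J); oneK <- matrix(1, 1, K)
  CA <- kronecker(cj, oneK)
  CB <- kronecker(oneJ, ck)
  CAB <- kronecker(cj, ck)
  rA <- .johansen(CA, tm, v, h)
  rB <- .johansen(CB, tm, v, h)
  rAB <- .johansen(CAB, tm, v, h)
  pA <- rA$p; pB <- rB$p; pAB <- rAB$p

  if (method == "bootstrap") {
    ctr <- mapply(function(x, s) x - s$tmean, cells, st, SIMPLIFY = FALSE)
    qs <- withr::with_seed(seed, {
      replicate(nboot, {
        bs <- lapply(ctr, function(x) sample(x, length(x), replace = TRUE))
        stb <- lapply(bs, trimmedMeanStats, trim = trim)
        tmb <- vapply(stb, `[[`, numeric(1), "tmean")
        vb <- vapply(stb, `[[`, numeric(1), "se2")
        hb <- vapply(stb, `[[`, numeric(1), "h")
        c(tryCatch(.johansen(CA, tmb, vb, hb)$Q, error = function(e) NA),
          tryCatch(.johansen(CB, tmb, vb, hb)$Q, error = function(e) NA),
          tryCatch(.johansen(CAB, tmb, vb, hb)$Q, error = function(e) NA))
      })
    })
    pA <- mean(qs[1, ] >= rA$Q, na.rm = TRUE)
    pB <- mean(qs[2, ] >= rB$Q, na.rm = TRUE)
    pAB <- mean(qs[3, ] >= rAB$Q, na.rm = TRUE)
  }
  new("TrimmedAnovaResult", qA = rA$Q, qB = rB$Q, qAB = rAB$Q,
      pA = pA, pB = pB, pAB = pAB, trim = trim, method = method)
}

#' Power of the two-sample t test
#'
#' `P(reject)` for a two-sample t test with `n` subjects per group and
#' standardized effect size `d`, from the noncentral t distribution
#' with `df = 2n - 2` and noncentrality `d * sqrt(n / 2)`.
#'
#' @param n subjects per group (>= 2).
#' @param d standardized effect size (Cohen's d).
#' @param alpha type-I error level in (0, 1).
#' @param sides `"two-sided"` or `"one-sided"`.
#' @return Power in [0, 1]; equals `alpha` at `d = 0`.
#' @export
powerTwoSampleT <- function(n, d, alpha = 0.05,
                            sides = c("two-sided", "one-sided")) {
  sides <- match.arg(sides)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n < 2) stop("n must be >= 2 per group")
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (sides == "two-sided") {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

#' Detectable effect size at a target power
#'
#' Solves `power(d; n, alpha, sides) = power` for the standardized
#' effect size `d` by monotone root finding on
#' [powerTwoSampleT()]. With 12 subjects per group, `alpha = 0.05`
#' and target power 0.8 (two-sided) this yields d = 1.2 to two
#' significant figures.
#'
#' @param n subjects per group.
#' @param alpha type-I error level.
#' @param power target power, in (alpha, 1).
#' @param sides `"two-sided"` or `"one-sided"`.
#' @return Cohen's d solving the power equation (inverse-consistent
#'   with [powerTwoSampleT()] to ~1e-8).
#' @export
effectSizeFromPower <- function(n, alpha = 0.05, power = 0.8,
                                sides = c("two-sided", "one-sided")) {
  sides <- match.arg(sides)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= alpha || power >= 1)
    stop("power must lie in (alpha, 1)")
  f <- function(d) powerTwoSampleT(n, d, alpha, sides) - power
  upper <- 1
  while (f(upper) < 0 && upper < 1e3) upper <- upper * 2
  if (f(upper) < 0) stop("unattainable power for this design")
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Median / min / max / IQR descriptive summary
#'
#' The study's numeric presentation of score and concentration data:
#' median, minimum to maximum, plus the interquartile range
#' (linear-interpolation quantiles).
#'
#' @param x numeric vector, non-empty.
#' @return Named numeric vector `median`, `min`, `max`, `iqr`.
#' @export
descriptiveSummary <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty input")
  c(median = stats::median(x), min = min(x), max = max(x),
    iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)))
}

#' Ordinal-stage frequency table
#'
#' Counts each ordinal stage per (group, time) cell, the tabulation
#' behind heat-map displays of disease-stage frequencies over
#' treatment and survival time. Counts conserve the number of
#' records; the `frequencies` component normalises each (group, time)
#' cell to its total.
#'
#' @param records score-record data.frame with columns `group`,
#'   `time_days`, `variable`, `value`.
#' @param variable which variable to tabulate; its values must be
#'   ordinal (integer-valued).
#' @return List with `counts` and `frequencies`, both 3D tables
#'   (stage x group x time).
#' @export
stageFrequencyTable <- function(records, variable) {
  need <- c("group", "time_days", "variable", "value")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  rec <- records[records$variable == variable, , drop = FALSE]
  if (!nrow(rec)) stop("no records for variable '", variable, "'")
  v <- rec$value
  if (any(!is.finite(v)) || any(abs(v - round(v)) > 1e-8))
    stop("variable '", variable, "' is not ordinal (non-integer values)")
  stage <- factor(round(v), levels = min(round(v)):max(round(v)))
  counts <- table(stage = stage, group = factor(rec$group),
                  time = factor(rec$time_days))
  tot <- apply(counts, c(2, 3), sum)
  freq <- sweep(counts, c(2, 3), pmax(tot, 1), "/")
  list(counts = counts, frequencies = freq)
}
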