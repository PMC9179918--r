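# Fixtures and independent oracles shared across the suite. All
# fixtures are generated in code; nothing binary ships with the
# package.

# Sierpinski carpet after `iters` subdivisions (3^iters square).
sierpinskiCarpet <- function(iters) {
  pat <- matrix(1, 3, 3)
  pat[2, 2] <- 0
  a <- matrix(1, 1, 1)
  for (i in seq_len(iters)) a <- kronecker(pat, a)
  a > 0
}

# Menger sponge after `iters` subdivisions (3^iters cube).
mengerSponge <- function(iters) {
  pat <- array(1, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    if (sum(c(i, j, k) == 2) >= 2) pat[i, j, k] <- 0
  a <- array(1, c(1, 1, 1))
  for (i in seq_len(iters)) a <- kronecker(pat, a)
  a > 0
}

# Random smooth blob mask: thresholded smoothed white noise, retried
# until non-empty.
randomBlobMask <- function(dim = c(16L, 16L, 8L), fill = 0.3) {
  repeat {
    f <- array(stats::rnorm(prod(dim)), dim)
    f <- gaussianBlur(f, fwhm = 3, spacing = c(1, 1, 1))
    m <- f > stats::quantile(f, 1 - fill)
    if (any(m)) return(m)
  }
}

# Brute-force trimmed mean / winsorized variance oracle: explicit
# sort-slice-clamp, no shared code with the implementation.
bruteTrimmedStats <- function(x, trim) {
  s <- sort(x)
  n <- length(s)
  g <- floor(trim * n)
  kept <- s[seq(g + 1, n - g)]
  tmean <- sum(kept) / length(kept)
  w <- s
  for (i in seq_len(n)) {
    if (i <= g) w[i] <- s[g + 1]
    if (i > n - g) w[i] <- s[n - g]
  }
  mw <- sum(w) / n
  winvar <- sum((w - mw)^2) / (n - 1)
  list(tmean = tmean, winvar = winvar, h = n - 2 * g)
}

# Independent nonlinear least-squares relaxometry oracles
# (direct minimisation of the signal-model residual via minpack.lm,
# generic starting values; no linearisation).
nlsT1Oracle <- function(S, flipAngles, tr) {
  a <- flipAngles * pi / 180
  df <- data.frame(S = S, sa = sin(a), ca = cos(a))
  fit <- try(minpack.lm::nlsLM(
    S ~ M0 * sa * (1 - exp(-tr / T1)) / (1 - exp(-tr / T1) * ca),
    data = df, start = list(M0 = 2 * max(S), T1 = 500),
    lower = c(0, 1), upper = c(Inf, 2e4),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NA_real_)
  stats::coef(fit)[["T1"]]
}

nlsT2Oracle <- function(S, echoTimes) {
  df <- data.frame(S = S, te = echoTimes)
  fit <- try(minpack.lm::nlsLM(
    S ~ S0 * exp(-te / T2), data = df,
    start = list(S0 = max(S), T2 = 20),
    lower = c(0, 0.1), upper = c(Inf, 5e3),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NA_real_)
  stats::coef(fit)[["T2"]]
}

# The study's acquisition parameters used throughout the suite.
STUDY_FLIP_ANGLES <- c(2, 5, 10, 15, 25, 45)
STUDY_ECHO_TIMES <- c(2.7, 4.1, 5.5, 6.9, 8.3, 9.7, 11.1, 12.5, 13.9,
                      15.3, 16.7, 18.1, 19.5, 20.9, 22.3, 23.7)
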