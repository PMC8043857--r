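# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain trapezoid integration, closed-form
# normal equations, combinatorial enumeration.

# trapezoid rule over a fine grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# GRM category probability written out longhand (cumulative logistic
# differences), scalar theta
oracleCatProb <- function(theta, a, b, k) {
  K <- length(b) + 1
  cum <- function(j) {
    if (j <= 0) return(1)
    if (j >= K) return(0)
    1 / (1 + exp(-a * (theta - b[j])))
  }
  cum(k) - cum(k + 1)
}

# marginal likelihood of one response vector by fine trapezoid integration
oracleMarginal <- function(x, a, b, lo = -8, hi = 8, n = 10001) {
  th <- seq(lo, hi, length.out = n)
  f <- dnorm(th)
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    f <- f * vapply(th, function(t) oracleCatProb(t, a[i], b[[i]], x[i]), 0)
  }
  trapz(th, f)
}

# posterior mean/sd of theta for one response vector
oraclePosterior <- function(x, a, b, lo = -8, hi = 8, n = 10001) {
  th <- seq(lo, hi, length.out = n)
  f <- dnorm(th)
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    f <- f * vapply(th, function(t) oracleCatProb(t, a[i], b[[i]], x[i]), 0)
  }
  Z <- trapz(th, f)
  m <- trapz(th, th * f) / Z
  v <- trapz(th, th^2 * f) / Z - m^2
  c(eap = m, psd = sqrt(v))
}

# closed-form OLS via normal equations: returns beta and se for column j
oracleOLS <- function(X, y, j) {
  XtXinv <- solve(t(X) %*% X)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(XtXinv))
  tst <- beta[j] / se[j]
  list(beta = unname(beta[j]), se = unname(se[j]), t = unname(tst),
       p = unname(2 * pt(-abs(tst), df)))
}

# exact HWE by direct enumeration with choose()-based weights
oracleHWE <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  n1 <- min(nA, na)
  hs <- seq(n1 %% 2, n1, by = 2)
  w <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2))
  }, 0)
  w <- w / sum(w)
  pObs <- w[hs == nAa]
  min(sum(w[w <= pObs * (1 + 1e-12)]), 1)
}

# brute-force BH step-up
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# small deterministic genotype fixture builder
toyGeno <- function(mat, chrom = "1", pos = NULL, rsq = NULL) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("v", seq_len(ncol(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("s", seq_len(nrow(mat)))
  vi <- data.frame(id = colnames(mat), chrom = chrom,
                   pos = if (is.null(pos)) seq_len(ncol(mat)) * 100 else pos,
                   ref = "A", alt = "G")
  if (!is.null(rsq)) vi$rsq <- rsq
  GenotypeData(mat, vi)
}
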