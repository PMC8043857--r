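## Samejima graded response model: category probabilities, marginal ML
## fitting by Bock-Aitkin EM, EAP scoring, and Fisher item information.

PROB_FLOOR <- 1e-10

#' Quadrature grid over the latent severity scale
#'
#' Equally spaced nodes with standard-normal weights, renormalised to sum
#' to one. The standard-normal prior on the latent trait is the model's
#' identification constraint, so all marginal integrals are taken against
#' it. 61 nodes on [-7, 7] give integration error far below reporting
#' precision; pass a denser grid when validating against continuous
#' integrals.
#'
#' @param n number of nodes.
#' @param range numeric length-2, latent-scale range covered.
#' @return list with `nodes` (numeric) and `weights` (positive, sum 1).
#' @examples
#' g <- latentQuadrature()
#' sum(g$weights)                       # 1
#' sum(g$nodes * g$weights)             # ~0 (prior mean)
#' @export
latentQuadrature <- function(n = 61L, range = c(-7, 7)) {
  if (n < 2L) stop("need at least 2 quadrature nodes")
  nodes <- seq(range[1], range[2], length.out = n)
  w <- stats::dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

#' Graded-response category probabilities
#'
#' Under Samejima's model the probability of scoring at or above category
#' k is a logistic in the latent trait,
#' \eqn{P^*_k(\theta) = 1 / (1 + e^{-a(\theta - b_k)})}, with boundary
#' conventions \eqn{P^*_0 = 1} and \eqn{P^*_K = 0}; the category
#' probabilities are successive differences
#' \eqn{P(X = k) = P^*_k - P^*_{k+1}}.
#'
#' @param theta numeric vector of latent values.
#' @param a positive discrimination.
#' @param b strictly increasing thresholds (length K-1 for K categories).
#' @return matrix `length(theta)` x K of probabilities; rows sum to 1.
#' @examples
#' p <- grmCategoryProbs(0, a = 1.5, b = c(-1, 0, 1))
#' rowSums(p)   # 1
#' @export
grmCategoryProbs <- function(theta, a, b) {
  if (any(diff(b) <= 0)) stop("thresholds must be strictly increasing")
  if (a <= 0) stop("discrimination must be positive")
  cum <- vapply(b, function(bk) stats::plogis(a * (theta - bk)),
                numeric(length(theta)))
  cum <- matrix(cum, nrow = length(theta))
  p <- cbind(1, cum) - cbind(cum, 0)
  dimnames(p) <- list(NULL, as.character(seq_len(ncol(p)) - 1L))
  p
}

## Cumulative P*(X >= k) for k = 1..K-1 at the grid nodes (Q x K-1).
grmCumProbs <- function(theta, a, b) {
  matrix(vapply(b, function(bk) stats::plogis(a * (theta - bk)),
                numeric(length(theta))), nrow = length(theta))
}

#' Fisher information of one graded item
#'
#' Samejima's item information
#' \deqn{I(\theta) = a^2 \sum_k \frac{[P^*_k(1-P^*_k) - P^*_{k+1}(1-P^*_{k+1})]^2}{P_k(\theta)}}
#' with the boundary cumulative probabilities 1 and 0. Equals the expected
#' negative second derivative of the category log-likelihood, and vanishes
#' in the tails.
#'
#' @param theta numeric vector of latent values.
#' @param a positive discrimination.
#' @param b strictly increasing thresholds.
#' @return numeric vector of non-negative information values.
#' @export
itemInformation <- function(theta, a, b) {
  p <- grmCategoryProbs(theta, a, b)
  cum <- cbind(1, grmCumProbs(theta, a, b), 0)
  w <- cum * (1 - cum)                      # P*_k (1 - P*_k), Q x (K+1)
  K <- ncol(p)
  num <- (w[, 1:K, drop = FALSE] - w[, 2:(K + 1), drop = FALSE])^2
  a^2 * rowSums(num / pmax(p, PROB_FLOOR))
}

#' Test information of a fitted model
#'
#' Sum of item informations over the items of a fit (optionally a subset).
#'
#' @param fit a [GRMFit-class].
#' @param theta numeric vector of latent values.
#' @param items optional character vector of item labels to include.
#' @return numeric vector, total information at each `theta`.
#' @export
testInformation <- function(fit, theta, items = NULL) {
  idx <- seq_along(fit@items)
  if (!is.null(items)) {
    idx <- match(items, fit@items)
    if (anyNA(idx)) stop("unknown items: ",
                         paste(items[is.na(idx)], collapse = ", "))
  }
  out <- numeric(length(theta))
  for (i in idx) out <- out + itemInformation(theta, fit@a[i], fit@b[[i]])
  out
}

## Log-likelihood matrix L[c, q] = sum_i log P(x_ci | theta_q); missing
## responses contribute factor 1. Scores must already be remapped to the
## fit's category coding.
grmLogLikMatrix <- function(sc, fit, nodes) {
  L <- matrix(0, nrow(sc), length(nodes))
  for (i in seq_along(fit@items)) {
    x <- sc[, fit@items[i]]
    obs <- which(!is.na(x))
    if (!length(obs)) next
    lp <- log(pmax(grmCategoryProbs(nodes, fit@a[i], fit@b[[i]]), PROB_FLOOR))
    L[obs, ] <- L[obs, ] + t(lp[, x[obs] + 1L, drop = FALSE])
  }
  L
}

## Remap raw panel scores to the (possibly collapsed) category coding of
## the fit; values outside the recorded labels are matched to the nearest
## lower label.
remapScores <- function(panel, fit) {
  sc <- scores(panel)[, fit@items, drop = FALSE]
  for (i in seq_along(fit@items)) {
    labs <- fit@catLabels[[i]]
    if (identical(labs, seq_along(labs) - 1L)) next
    x <- sc[, i]
    sc[, i] <- as.integer(findInterval(x, labs) - 1L)
  }
  sc
}

#' Marginal log-likelihood of a panel under a graded-response fit
#'
#' \eqn{\sum_c \log \int \prod_i P(x_{ci} \mid \theta)\,\phi(\theta)\,d\theta},
#' approximated on the quadrature grid. Missing responses are treated as
#' missing at random and contribute a factor of 1.
#'
#' @param panel a [PathologyPanel-class] whose items cover the fit's items.
#' @param fit a [GRMFit-class].
#' @param grid quadrature grid from [latentQuadrature()].
#' @return the marginal log-likelihood (scalar).
#' @export
grmMarginalLogLik <- function(panel, fit, grid = latentQuadrature()) {
  if (!length(grid$nodes)) stop("empty quadrature grid")
  if (!length(fit@items)) return(0)
  if (!all(fit@items %in% colnames(scores(panel))))
    stop("fit parameters must cover all panel items")
  L <- grmLogLikMatrix(remapScores(panel, fit), fit, grid$nodes)
  lw <- sweep(L, 2, log(grid$weights), `+`)
  m <- apply(lw, 1, max)
  sum(m + log(rowSums(exp(lw - m))))
}

#' Expected a posteriori latent severity scores
#'
#' Posterior mean and SD of the latent trait per case under the
#' standard-normal prior. A case with no observed items falls back to the
#' prior exactly (EAP 0, posterior SD 1).
#'
#' @param panel a [PathologyPanel-class].
#' @param fit a [GRMFit-class] fitted on (a superset of) the panel's items.
#' @param grid quadrature grid from [latentQuadrature()].
#' @return data.frame with columns `case`, `eap`, `psd`, `nObserved`.
#' @export
eapScores <- function(panel, fit, grid = latentQuadrature()) {
  sc <- remapScores(panel, fit)
  L <- grmLogLikMatrix(sc, fit, grid$nodes)
  lw <- sweep(L, 2, log(grid$weights), `+`)
  m <- apply(lw, 1, max)
  post <- exp(lw - m)
  post <- post / rowSums(post)
  eap <- as.numeric(post %*% grid$nodes)
  ex2 <- as.numeric(post %*% grid$nodes^2)
  psd <- sqrt(pmax(ex2 - eap^2, 0))
  nObs <- rowSums(!is.na(sc))
  eap[nObs == 0] <- 0
  psd[nObs == 0] <- 1
  data.frame(case = rownames(sc), eap = eap, psd = psd, nObserved = nObs)
}

## --- fitting ---------------------------------------------------------------

## Internal parameter transform: par = (log a, b1, log diff(b)...) keeps
## a > 0 and the thresholds strictly increasing during optimisation.
parToAB <- function(par) {
  a <- min(max(exp(par[1]), 1e-4), 100)
  b <- cumsum(c(par[2], pmax(exp(par[-(1:2)]), 1e-6)))
  list(a = a, b = b)
}
abToPar <- function(a, b) c(log(a), b[1], if (length(b) > 1) log(diff(b)))

## Expected complete-data log-likelihood for one item given expected
## counts r (Q x K) at the nodes.
itemEStepObjective <- function(par, r, nodes) {
  ab <- parToAB(par)
  if (any(!is.finite(c(ab$a, ab$b)))) return(1e10)
  P <- grmCategoryProbs(nodes, ab$a, ab$b)
  -sum(r * log(pmax(P, PROB_FLOOR)))
}

## analytic gradient of the (negated) expected complete-data
## log-likelihood w.r.t. the transformed parameters
itemEStepGradient <- function(par, r, nodes) {
  ab <- parToAB(par)
  a <- ab$a; b <- ab$b
  K <- length(b) + 1L
  cum <- cbind(1, grmCumProbs(nodes, a, b), 0)       # Q x (K+1)
  P <- cum[, 1:K, drop = FALSE] - cum[, 2:(K + 1), drop = FALSE]
  Rr <- r / pmax(P, PROB_FLOOR)
  W <- cum * (1 - cum)                               # P* (1 - P*)
  ## d/da: via d P*_j / da = (theta - b_j) W_j, zero at the boundaries
  Dmat <- cbind(0, outer(nodes, b, `-`) * W[, 2:K, drop = FALSE], 0)
  dA <- sum(Rr * (Dmat[, 1:K, drop = FALSE] - Dmat[, 2:(K + 1), drop = FALSE]))
  ## d/db_j = a sum_q W_j (r_{j-1}/P_{j-1} - r_j/P_j)
  dB <- vapply(seq_len(K - 1L), function(j)
    a * sum(W[, j + 1L] * (Rr[, j] - Rr[, j + 1L])), 0)
  ## chain rule to (log a, b1, log spacings)
  g <- c(dA * a, sum(dB),
         if (K > 2L) rev(cumsum(rev(dB)))[-1] * exp(par[-(1:2)]))
  -g
}

## box constraints on (log a, b1, log spacings) keep the M-step away from
## degenerate items (a -> 0 or Inf, runaway thresholds)
mstepLower <- function(K) c(log(0.01), -30, rep(-8, K - 2L))
mstepUpper <- function(K) c(log(50), 30, rep(5, K - 2L))

#' Fit Samejima's graded response model by marginal maximum likelihood
#'
#' Bock-Aitkin EM: the E-step computes per-case posterior weights over the
#' quadrature nodes; the M-step maximises each item's expected
#' complete-data log-likelihood (an ordinal-logistic subproblem, solved
#' quasi-Newton on an unconstrained slope / log-spacing parameterisation
#' that enforces positive discrimination and monotone thresholds).
#' Deterministic given data and settings.
#'
#' Items observed in fewer than two categories carry no information and
#' are excluded with a warning (or an error under `strict = TRUE`).
#' Categories never observed for an item are collapsed for fitting; the
#' mapping back to the original 0-based codes is recorded in `catLabels`.
#'
#' @param panel a [PathologyPanel-class].
#' @param items optional subset of item labels to fit (default: all).
#' @param grid quadrature grid; default 61 nodes on [-7, 7].
#' @param tol EM stops when the largest absolute parameter change drops
#'   below this (default 1e-4).
#' @param maxIter maximum EM iterations (default 500).
#' @param minCases minimum number of cases required (default 20).
#' @param strict error (rather than warn) on uninformative items.
#' @return a [GRMFit-class].
#' @examples
#' set.seed(1)
#' sim <- simulateGRMPanel(n = 200, a = c(1.2, 1.8), b = list(c(-1, 0, 1), c(-0.5, 0.5, 1.5)))
#' fit <- fitGRM(sim$panel)
#' discriminations(fit)
#' @export
fitGRM <- function(panel, items = NULL, grid = latentQuadrature(),
                   tol = 1e-4, maxIter = 500L, minCases = 20L,
                   strict = FALSE) {
  sc <- scores(panel)
  if (!is.null(items)) {
    miss <- setdiff(items, colnames(sc))
    if (length(miss)) stop("unknown items: ", paste(miss, collapse = ", "))
    sc <- sc[, items, drop = FALSE]
  }
  if (nrow(sc) < minCases)
    stop(sprintf("need at least %d cases, have %d", minCases, nrow(sc)))

  ## screen items: >= 2 observed categories
  nLev <- apply(sc, 2, function(x) length(unique(x[!is.na(x)])))
  dropped <- colnames(sc)[nLev < 2L]
  if (length(dropped)) {
    msg <- paste("items with a single observed category excluded:",
                 paste(dropped, collapse = ", "))
    if (strict) stop(msg)
    warning(msg)
    sc <- sc[, nLev >= 2L, drop = FALSE]
  }
  if (ncol(sc) < 1L) stop("no informative items left")

  ## collapse unobserved categories; record original labels
  catLabels <- vector("list", ncol(sc))
  for (i in seq_len(ncol(sc))) {
    labs <- sort(unique(sc[!is.na(sc[, i]), i]))
    catLabels[[i]] <- as.integer(labs)
    if (!identical(as.integer(labs), seq_along(labs) - 1L))
      sc[, i] <- as.integer(match(sc[, i], labs) - 1L)
  }

  nodes <- grid$nodes
  Q <- length(nodes)
  nIt <- ncol(sc)

  ## starting values: a = 1, b_k from inverse-normal cumulative frequencies
  a <- rep(1, nIt)
  b <- vector("list", nIt)
  for (i in seq_len(nIt)) {
    x <- sc[!is.na(sc[, i]), i]
    K <- length(catLabels[[i]])
    cumBelow <- vapply(seq_len(K - 1L), function(k) mean(x < k), 0)
    bk <- stats::qnorm(pmin(pmax(cumBelow, 0.01), 0.99))
    ## enforce strict increase
    for (k in seq_along(bk)[-1]) bk[k] <- max(bk[k], bk[k - 1] + 1e-3)
    b[[i]] <- bk
  }

  ## precompute response indicators per item: list of (case index by category)
  catIdx <- lapply(seq_len(nIt), function(i) {
    K <- length(catLabels[[i]])
    lapply(seq_len(K) - 1L, function(k) which(!is.na(sc[, i]) & sc[, i] == k))
  })

  converged <- FALSE
  iter <- 0L
  logw <- log(grid$weights)
  repeat {
    iter <- iter + 1L
    ## E-step: posterior over nodes per case
    L <- matrix(0, nrow(sc), Q)
    for (i in seq_len(nIt)) {
      lp <- log(pmax(grmCategoryProbs(nodes, a[i], b[[i]]), PROB_FLOOR))
      x <- sc[, i]
      obs <- which(!is.na(x))
      if (length(obs))
        L[obs, ] <- L[obs, ] + t(lp[, x[obs] + 1L, drop = FALSE])
    }
    lw <- sweep(L, 2, logw, `+`)
    m <- apply(lw, 1, max)
    post <- exp(lw - m)
    post <- post / rowSums(post)

    ## M-step: per-item ordinal-logistic subproblem, warm-started
    delta <- 0
    for (i in seq_len(nIt)) {
      K <- length(catLabels[[i]])
      r <- matrix(0, Q, K)
      for (k in seq_len(K))
        if (length(catIdx[[i]][[k]]))
          r[, k] <- colSums(post[catIdx[[i]][[k]], , drop = FALSE])
      opt <- stats::optim(abToPar(a[i], b[[i]]), itemEStepObjective,
                          gr = itemEStepGradient,
                          r = r, nodes = nodes, method = "L-BFGS-B",
                          lower = mstepLower(K), upper = mstepUpper(K),
                          control = list(maxit = 100))
      ab <- parToAB(opt$par)
      delta <- max(delta, abs(ab$a - a[i]), abs(ab$b - b[[i]]))
      a[i] <- ab$a
      b[[i]] <- ab$b
    }
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations (last change %.2g)",
                    iter, delta))

  fit <- new("GRMFit", items = colnames(sc), a = a, b = b,
             catLabels = catLabels, logLik = NA_real_, iterations = iter,
             converged = converged, dropped = dropped)
  subPanel <- new("PathologyPanel",
                  scores = scores(panel)[, fit@items, drop = FALSE],
                  items = itemInfo(panel)[match(fit@items, itemInfo(panel)$item), ,
                                          drop = FALSE],
                  nCat = panel@nCat)
  fit@logLik <- grmMarginalLogLik(subPanel, fit, grid)
  fit
}

#' Area under region-wise information curves
#'
#' Sums item information within each region group, integrates over the
#' latent range by the trapezoid rule, and ranks regions by that area --
#' the region-informativeness summary used to prioritise anatomical
#' structures.
#'
#' @param fit a [GRMFit-class].
#' @param grouping named character vector, item label -> region label;
#'   must cover all fitted items to be grouped. Items of the fit missing
#'   from the grouping are ignored with a warning.
#' @param thetaRange latent range of integration (default [-4, 4]).
#' @param nGrid number of grid points (default 201).
#' @return named numeric vector of per-region areas, sorted descending.
#' @export
informationCurveAUC <- function(fit, grouping, thetaRange = c(-4, 4),
                                nGrid = 201L) {
  theta <- seq(thetaRange[1], thetaRange[2], length.out = nGrid)
  h <- diff(theta[1:2])
  ungrouped <- setdiff(fit@items, names(grouping))
  if (length(ungrouped))
    warning("items without a region group ignored: ",
            paste(ungrouped, collapse = ", "))
  regions <- unique(grouping[names(grouping) %in% fit@items])
  if (!length(regions)) stop("grouping covers no fitted item")
  auc <- vapply(regions, function(rg) {
    its <- names(grouping)[grouping == rg]
    its <- intersect(its, fit@items)
    if (!length(its)) return(NA_real_)
    y <- testInformation(fit, theta, items = its)
    h * (sum(y) - (y[1] + y[length(y)]) / 2)
  }, 0)
  empty <- is.na(auc)
  if (any(empty)) {
    warning("empty region groups excluded: ",
            paste(regions[empty], collapse = ", "))
    auc <- auc[!empty]
  }
  sort(auc, decreasing = TRUE)
}

#' Plot region-wise information curves
#'
#' @param fit a [GRMFit-class].
#' @param grouping named character vector, item -> region.
#' @param thetaRange latent range (default [-4, 4]).
#' @param nGrid grid points (default 201).
#' @param main plot title.
#' @return invisibly, the matrix of per-region curves.
#' @export
plotInformationCurves <- function(fit, grouping, thetaRange = c(-4, 4),
                                  nGrid = 201L, main = "Item information by region") {
  theta <- seq(thetaRange[1], thetaRange[2], length.out = nGrid)
  regions <- unique(grouping[names(grouping) %in% fit@items])
  curves <- sapply(regions, function(rg) {
    its <- intersect(names(grouping)[grouping == rg], fit@items)
    testInformation(fit, theta, items = its)
  })
  graphics::matplot(theta, curves, type = "l", lty = 1,
                    col = grDevices::hcl.colors(length(regions), "Dark 3"),
                    xlab = expression(theta), ylab = "Information", main = main)
  graphics::legend("topright", legend = regions, lty = 1, cex = 0.6,
                   col = grDevices::hcl.colors(length(regions), "Dark 3"))
  invisible(curves)
}
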