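# Graded response model: probabilities, marginal likelihood, EAP scoring,
# item information, fitting.

test_that("category probabilities follow the cumulative-logistic model", {
  # logistic at its location
  p <- grmCategoryProbs(0, a = 1, b = c(0, 1, 2))
  expect_equal(1 - unname(p[1, 1]), 0.5)   # P(X >= 1) at theta = b_1

  # frozen values from direct evaluation of the cumulative formula
  p <- grmCategoryProbs(0, a = 1.5, b = c(-1, 0, 1))
  expect_equal(round(as.numeric(p), 4), c(0.1824, 0.3176, 0.3176, 0.1824))

  # rows sum to one and match the longhand oracle over random items
  set.seed(11)
  for (rep in 1:20) {
    a <- runif(1, 0.3, 3)
    b <- sort(rnorm(3, sd = 1.5))
    while (any(diff(b) <= 0)) b <- sort(rnorm(3, sd = 1.5))
    th <- runif(5, -4, 4)
    P <- grmCategoryProbs(th, a, b)
    expect_equal(rowSums(P), rep(1, 5))
    for (k in 0:3)
      expect_equal(P[, k + 1],
                   vapply(th, function(t) oracleCatProb(t, a, b, k), 0),
                   tolerance = 1e-12)
  }
})

test_that("cumulative tail probabilities are monotone in theta and category", {
  set.seed(21)
  th <- seq(-5, 5, length.out = 41)
  for (rep in 1:10) {
    a <- runif(1, 0.3, 3)
    b <- cumsum(c(rnorm(1), runif(2, 0.2, 1.5)))
    P <- grmCategoryProbs(th, a, b)
    cum <- t(apply(P[, 4:1], 1, cumsum))[, 4:1]  # P(X >= k), k = 0..3
    expect_true(all(diff(t(cum)) <= 1e-12))      # non-increasing in k
    expect_true(all(apply(cum[, -1], 2, diff) >= -1e-12))  # non-decr in theta
  }
})

test_that("invalid item parameters are rejected", {
  expect_error(grmCategoryProbs(0, 1, c(1, 0.5)), "strictly increasing")
  expect_error(grmCategoryProbs(0, -1, c(0, 1)), "positive")
})

test_that("marginal log-likelihood matches a fine trapezoid oracle", {
  a <- 1.4; b <- list(c(-0.8, 0.3, 1.2))
  sc <- matrix(2L, 1, 1, dimnames = list("c1", "r__l"))
  panel <- PathologyPanel(sc)
  fit <- new("GRMFit", items = "r__l", a = a, b = b, catLabels = list(0:3),
             logLik = 0, iterations = 1L, converged = TRUE,
             dropped = character())
  fine <- latentQuadrature(10001L, c(-8, 8))
  got <- grmMarginalLogLik(panel, fit, fine)
  expect_equal(got, log(oracleMarginal(2L, a, b)), tolerance = 1e-6)

  # several cases: sum over cases, invariant to case order
  sc2 <- matrix(c(0L, 3L, 1L), 3, 1, dimnames = list(paste0("c", 1:3), "r__l"))
  p2 <- PathologyPanel(sc2)
  got2 <- grmMarginalLogLik(p2, fit, fine)
  expect_equal(got2, sum(sapply(c(0L, 3L, 1L),
                                function(x) log(oracleMarginal(x, a, b)))),
               tolerance = 1e-6)
  p2perm <- PathologyPanel(sc2[c(3, 1, 2), , drop = FALSE])
  expect_equal(grmMarginalLogLik(p2perm, fit, fine), got2)

  # empty grid errors; zero items gives the empty product
  expect_error(grmMarginalLogLik(panel, fit, list(nodes = numeric(),
                                                  weights = numeric())),
               "empty")
})

test_that("EAP scores match the posterior-moment oracle and the prior fallback", {
  a <- c(1.2, 2.0); b <- list(c(-1, 0, 1), c(-0.5, 0.5, 1.5))
  fit <- new("GRMFit", items = c("i1__x", "i2__x"), a = a, b = b,
             catLabels = list(0:3, 0:3), logLik = 0, iterations = 1L,
             converged = TRUE, dropped = character())
  sc <- matrix(c(3L, NA, NA, NA, NA, 2L), 3, 2,
               dimnames = list(paste0("c", 1:3), c("i1__x", "i2__x")))
  panel <- PathologyPanel(sc)
  fine <- latentQuadrature(10001L, c(-8, 8))
  es <- eapScores(panel, fit, fine)

  o1 <- oraclePosterior(c(3L, NA), a, b)
  o3 <- oraclePosterior(c(NA, 2L), a, b)
  expect_equal(es$eap[1], unname(o1["eap"]), tolerance = 1e-6)
  expect_equal(es$psd[1], unname(o1["psd"]), tolerance = 1e-6)
  expect_equal(es$eap[3], unname(o3["eap"]), tolerance = 1e-6)

  # all-missing case falls back to the prior exactly
  expect_identical(es$eap[2], 0)
  expect_identical(es$psd[2], 1)
  expect_true(all(es$psd <= 1 + 1e-6))
})

test_that("EAP is monotone in the response vector (exhaustive 2-item grid)", {
  a <- c(1.5, 0.9); b <- list(c(-1, 0, 1), c(-0.6, 0.4, 1.1))
  fit <- new("GRMFit", items = c("i1__x", "i2__x"), a = a, b = b,
             catLabels = list(0:3, 0:3), logLik = 0, iterations = 1L,
             converged = TRUE, dropped = character())
  combos <- expand.grid(x1 = 0:3, x2 = 0:3)
  sc <- as.matrix(combos)
  dimnames(sc) <- list(paste0("c", seq_len(nrow(sc))), c("i1__x", "i2__x"))
  storage.mode(sc) <- "integer"
  es <- eapScores(PathologyPanel(sc), fit)
  eap <- matrix(es$eap, 4, 4)
  # component-wise larger responses never decrease the EAP
  expect_true(all(apply(eap, 2, diff) > 0))
  expect_true(all(apply(eap, 1, diff) > 0))
})

test_that("item information matches the finite-difference Fisher oracle", {
  a <- 1.7; b <- c(-1.2, 0.1, 0.9)
  th <- seq(-3, 3, by = 0.5)
  # -E[d^2/dtheta^2 log P(X|theta)] via central differences per category
  h <- 1e-4
  fd <- vapply(th, function(t) {
    Pm <- grmCategoryProbs(t - h, a, b)
    P0 <- grmCategoryProbs(t, a, b)
    Pp <- grmCategoryProbs(t + h, a, b)
    d2 <- (log(Pp) - 2 * log(P0) + log(Pm)) / h^2
    -sum(P0 * d2)
  }, 0)
  expect_equal(itemInformation(th, a, b), fd, tolerance = 1e-4)

  # tail decay and the a^2 scaling of the peak
  expect_lt(itemInformation(10, a, b), 1e-3)
  expect_lt(itemInformation(-10, a, b), 1e-3)
  grid <- seq(-4, 4, length.out = 161)
  expect_gt(max(itemInformation(grid, 2 * a, b)),
            max(itemInformation(grid, a, b)))
})

test_that("test information is the sum of item informations", {
  a <- c(1.1, 2.2); b <- list(c(-1, 0, 1), c(0, 0.7, 1.5))
  fit <- new("GRMFit", items = c("i1__x", "i2__x"), a = a, b = b,
             catLabels = list(0:3, 0:3), logLik = 0, iterations = 1L,
             converged = TRUE, dropped = character())
  th <- seq(-3, 3, by = 0.25)
  expect_equal(testInformation(fit, th),
               itemInformation(th, a[1], b[[1]]) +
                 itemInformation(th, a[2], b[[2]]))
})

test_that("EM fitting recovers simulated item parameters", {
  set.seed(101)
  nIt <- 10
  a <- runif(nIt, 0.8, 2.5)
  b <- lapply(seq_len(nIt), function(i)
    runif(1, -1, 1) + c(-1, 0, 1) * runif(1, 0.6, 1.2))
  sim <- simulateGRMPanel(2000, a, b, seed = 102)
  fit <- fitGRM(sim$panel)
  expect_true(fit@converged)
  expect_gt(cor(unname(discriminations(fit)), a), 0.95)
  expect_lt(sqrt(mean((unlist(thresholds(fit)) - unlist(b))^2)), 0.15)
  es <- eapScores(sim$panel, fit)
  expect_gt(cor(es$eap, sim$theta), 0.9)
})

test_that("EM reaches at least the best grid-searched likelihood on a toy panel", {
  set.seed(55)
  a <- c(1.3, 1.0); b <- list(c(-0.5, 0.7), c(0, 1))
  sim <- simulateGRMPanel(150, a, b, seed = 56)
  fit <- fitGRM(sim$panel, minCases = 10)
  grid <- latentQuadrature()
  emLL <- grmMarginalLogLik(sim$panel, fit, grid)
  # exhaustive coarse search over both items' (a, b1, b2)
  aG <- c(0.5, 1, 1.5, 2)
  b1G <- c(-1, -0.5, 0, 0.5)
  dG <- c(0.5, 1, 1.5)
  best <- -Inf
  for (a1 in aG) for (b11 in b1G) for (d1 in dG)
    for (a2 in aG) for (b21 in b1G) for (d2 in dG) {
      f <- new("GRMFit", items = fit@items, a = c(a1, a2),
               b = list(c(b11, b11 + d1), c(b21, b21 + d2)),
               catLabels = fit@catLabels, logLik = 0, iterations = 1L,
               converged = TRUE, dropped = character())
      best <- max(best, grmMarginalLogLik(sim$panel, f, grid))
    }
  expect_gte(emLL, best - 1e-4)
})

test_that("uninformative items are excluded (or fatal under strict mode)", {
  set.seed(60)
  sim <- simulateGRMPanel(100, c(1.5, 1.5), list(c(-1, 0, 1), c(-1, 0, 1)),
                          seed = 61)
  sc <- scores(sim$panel)
  sc[, 2] <- 0L   # constant item
  panel <- PathologyPanel(sc)
  expect_warning(fit <- fitGRM(panel, minCases = 10), "single observed category")
  expect_identical(fit@dropped, colnames(sc)[2])
  expect_error(fitGRM(panel, minCases = 10, strict = TRUE),
               "single observed category")
})

test_that("parameter recovery holds across seeded replicates", {
  # moderate-size replicates: discrimination always positive, thresholds close
  rmse <- numeric(5)
  for (r in 1:5) {
    set.seed(200 + r)
    nIt <- 8
    a <- runif(nIt, 0.8, 2.5)
    b <- lapply(seq_len(nIt), function(i)
      runif(1, -1, 1) + c(-1, 0, 1) * runif(1, 0.6, 1.2))
    sim <- simulateGRMPanel(600, a, b, seed = 300 + r)
    fit <- fitGRM(sim$panel)
    expect_true(all(discriminations(fit) > 0))
    rmse[r] <- sqrt(mean((unlist(thresholds(fit)) - unlist(b))^2))
  }
  expect_lt(mean(rmse), 0.2)
})

test_that("information-curve areas match a fine-grid oracle and rank weak regions last", {
  a <- c(2.2, 1.8, 0.02, 1.1)
  b <- list(c(-1, 0, 1), c(-0.5, 0.5, 1.5), c(-1, 0, 1), c(0, 1, 2))
  items <- c("strong1__x", "strong2__x", "flat__x", "mid__x")
  fit <- new("GRMFit", items = items, a = a, b = b,
             catLabels = rep(list(0:3), 4), logLik = 0, iterations = 1L,
             converged = TRUE, dropped = character())
  grouping <- setNames(c("strong", "strong", "flat", "mid"), items)
  auc <- informationCurveAUC(fit, grouping, nGrid = 201L)
  aucFine <- informationCurveAUC(fit, grouping, nGrid = 20001L)
  expect_equal(auc, aucFine[names(auc)], tolerance = 1e-3)
  # near-zero-discrimination region ranks last with negligible area
  expect_identical(names(auc)[length(auc)], "flat")
  expect_lt(auc[["flat"]], 0.01)
})

test_that("collapsed unobserved categories keep original labels", {
  set.seed(70)
  # responses only in {0, 1, 3}: category 2 never observed
  sc <- matrix(sample(c(0L, 1L, 3L), 400, replace = TRUE,
                      prob = c(0.4, 0.4, 0.2)), 200, 2,
               dimnames = list(NULL, c("r1__l", "r2__l")))
  # second item well-behaved
  sc[, 2] <- sample(0:3, 200, replace = TRUE)
  panel <- PathologyPanel(sc)
  fit <- fitGRM(panel, minCases = 10, tol = 1e-3, maxIter = 2000L)
  expect_identical(fit@catLabels[[1]], c(0L, 1L, 3L))
  expect_length(fit@b[[1]], 2)  # 3 observed categories -> 2 thresholds
  # scoring still accepts the raw panel
  es <- eapScores(panel, fit)
  expect_false(anyNA(es$eap))
})
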