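# Additive-model GWAS, combined analysis, stage-2 selection, Bonferroni,
# cis-eQTL with BH q-values.

test_that("per-variant OLS matches the closed-form normal-equations oracle", {
  # 6-case hand example, no covariates
  g <- c(0, 0, 1, 1, 2, 2)
  y <- c(0.1, -0.1, 0.5, 0.3, 0.9, 0.7)
  geno <- toyGeno(matrix(g, 6, 1))
  lt <- setNames(y, paste0("s", 1:6))
  tab <- qtGwas(lt, geno)
  o <- oracleOLS(cbind(1, g), y, 2)
  expect_equal(tab$BETA, o$beta, tolerance = 1e-10)
  expect_equal(tab$SE, o$se, tolerance = 1e-10)
  expect_equal(tab$P, o$p, tolerance = 1e-10)
  expect_equal(tab$N, 6L)

  # property check: random small instances with covariates
  set.seed(90)
  for (rep in 1:15) {
    n <- sample(10:50, 1)
    k <- sample(0:5, 1)
    gg <- rbinom(n, 2, 0.3)
    X <- if (k) matrix(rnorm(n * k), n) else NULL
    yy <- rnorm(n)
    if (var(gg) == 0) next
    geno <- toyGeno(matrix(gg, n, 1))
    cov <- if (k) as.data.frame(X) else NULL
    if (!is.null(cov)) rownames(cov) <- paste0("s", 1:n)
    tab <- qtGwas(setNames(yy, paste0("s", 1:n)), geno, cov = cov)
    o <- oracleOLS(cbind(1, gg, X), yy, 2)
    expect_equal(tab$BETA, o$beta, tolerance = 1e-10)
    expect_equal(tab$SE, o$se, tolerance = 1e-10)
  }
})

test_that("degenerate variants yield flagged NA rows", {
  set.seed(91)
  d <- cbind(rbinom(20, 2, 0.4), rep(1, 20))
  geno <- toyGeno(d)
  lt <- setNames(rnorm(20), paste0("s", 1:20))
  tab <- qtGwas(lt, geno)
  expect_true(is.na(tab$BETA[2]))
  expect_identical(tab$NOTE[2], "constant-dosage")
  expect_false(is.na(tab$BETA[1]))

  # n below covariates + 2
  geno3 <- toyGeno(matrix(c(0, 1, 2), 3, 1))
  cov <- data.frame(a = rnorm(3), b = rnorm(3), row.names = paste0("s", 1:3))
  tab3 <- qtGwas(setNames(rnorm(3), paste0("s", 1:3)), geno3, cov = cov)
  expect_true(is.na(tab3$BETA))
})

test_that("null simulation is calibrated: type-I error and KS uniformity", {
  set.seed(92)
  n <- 400
  d <- vapply(runif(600, 0.1, 0.5), function(p) rbinom(n, 2, p), numeric(n))
  geno <- toyGeno(d)
  lt <- setNames(rnorm(n), paste0("s", 1:n))
  tab <- qtGwas(lt, geno)
  expect_lt(abs(mean(tab$P < 0.05) - 0.05), 0.01)
  expect_gt(ks.test(tab$P, "punif")$p.value, 0.01)
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 559348), 0.05 / 559348)
  expect_lte(bonferroniThreshold(0.05, 559348), 9.0e-8)
  expect_equal(bonferroniThreshold(0.05, 559348), 8.94e-8, tolerance = 1e-3)
})

test_that("stage-2 selection prunes LD greedily by ascending P", {
  set.seed(93)
  n <- 300
  # 3 LD blocks of 4 + 8 independents
  mkBlock <- function(p) {
    core <- rbinom(n, 2, p)
    sapply(1:4, function(i) {
      flip <- runif(n) < 0.02
      ifelse(flip, rbinom(n, 2, p), core)
    })
  }
  d <- cbind(mkBlock(0.3), mkBlock(0.4), mkBlock(0.25),
             vapply(runif(8, 0.2, 0.5), function(p) rbinom(n, 2, p),
                    numeric(n)))
  geno <- toyGeno(d)
  P <- runif(20, 1e-9, 1e-6)            # all below the cut
  assoc <- data.frame(ID = colnames(dosages(geno)), TRAIT = "LT", P = P)
  sel <- selectStage2Snps(assoc, geno, pCut = 1e-5, ldR2Cut = 0.95)

  # brute-force check of the greedy rule
  ord <- assoc$ID[order(assoc$P)]
  kept <- character()
  for (id in ord) {
    ok <- TRUE
    for (k in kept) {
      r2 <- cor(dosages(geno)[, id], dosages(geno)[, k])^2
      if (!is.na(r2) && r2 > 0.95) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, id)
  }
  expect_identical(sel, kept)

  # two perfectly correlated hits: smaller P retained
  d2 <- cbind(rbinom(50, 2, 0.5), 0)
  d2[, 2] <- d2[, 1]
  geno2 <- toyGeno(d2)
  a2 <- data.frame(ID = c("v1", "v2"), TRAIT = "LT", P = c(1e-7, 1e-6))
  expect_identical(selectStage2Snps(a2, geno2), "v1")
  # nothing below the cut -> empty
  a3 <- data.frame(ID = c("v1", "v2"), TRAIT = "LT", P = c(0.1, 0.2))
  expect_identical(selectStage2Snps(a3, geno2), character())
})

test_that("inverse-variance meta matches the hand formula and beats both stages", {
  s1 <- data.frame(CHR = "1", POS = 1L, ID = "v1", A1 = "G", A2 = "A",
                   TRAIT = "LT", BETA = 0.2, SE = 0.1, T = 2, P = 0.05,
                   N = 100L, STAGE = "stage1", NOTE = "")
  s2 <- s1; s2$BETA <- 0.1; s2$STAGE <- "stage2"
  m <- combineStages(s1, s2, method = "ivw")
  expect_equal(m$BETA, 0.15)
  expect_equal(m$SE, 0.1 / sqrt(2), tolerance = 1e-4)
  expect_equal(round(m$SE, 4), 0.0707)
  expect_lte(m$SE, min(s1$SE, s2$SE))

  # variant present in one stage only: passed through, flagged
  s2b <- s2; s2b$ID <- "v2"
  m2 <- combineStages(s1, s2b, method = "ivw")
  expect_setequal(m2$NOTE, "single-stage")
})

test_that("pooled combination equals a direct OLS refit on the merged data", {
  set.seed(94)
  n1 <- 120; n2 <- 80
  g1 <- rbinom(n1, 2, 0.3); g2 <- rbinom(n2, 2, 0.3)
  beta <- 0.3
  y1 <- beta * g1 + rnorm(n1); y2 <- 0.5 + beta * g2 + rnorm(n2)
  geno1 <- GenotypeData(matrix(g1, dimnames = list(paste0("a", 1:n1), "v1")),
                        data.frame(id = "v1", chrom = "1", pos = 100,
                                   ref = "A", alt = "G"))
  geno2 <- GenotypeData(matrix(g2, dimnames = list(paste0("b", 1:n2), "v1")),
                        data.frame(id = "v1", chrom = "1", pos = 100,
                                   ref = "A", alt = "G"))
  lt1 <- setNames(y1, paste0("a", 1:n1)); lt2 <- setNames(y2, paste0("b", 1:n2))
  t1 <- qtGwas(lt1, geno1, trait = "LT", stage = "stage1")
  t2 <- qtGwas(lt2, geno2, trait = "LT", stage = "stage2")
  comb <- combineStages(t1, t2, method = "pooled",
                        stageData = list(list(lt = lt1, geno = geno1),
                                         list(lt = lt2, geno = geno2)))
  o <- oracleOLS(cbind(1, c(g1, g2), c(rep(0, n1), rep(1, n2))),
                 c(y1, y2), 2)
  expect_equal(comb$BETA, o$beta, tolerance = 1e-10)
  expect_equal(comb$SE, o$se, tolerance = 1e-10)

  # pooled and IVW agree reasonably on homogeneous stages
  meta <- combineStages(t1, t2, method = "ivw")
  expect_lt(abs(meta$BETA - comb$BETA), 0.1 * abs(comb$BETA) + 0.02)
  # meta of a single stage is that stage
  m1 <- combineStages(t1, t1[0, ], method = "ivw")
  expect_equal(m1$BETA, t1$BETA)
  expect_identical(m1$NOTE, "single-stage")
})

test_that("BH q-values match the brute-force step-up and are rank-monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))   # the step-up collapses
  set.seed(95)
  for (rep in 1:10) {
    p <- runif(sample(3:30, 1))
    q <- p.adjust(p, "BH")
    expect_equal(q, oracleBH(p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("cis window is inclusive at exactly the boundary", {
  # gene body [2e6, 2.05e6]; window 1 Mb
  pos <- c(1e6, 1e6 - 1, 2.05e6 + 1e6, 2.05e6 + 1e6 + 1, 2e6)
  set.seed(96)
  d <- matrix(rbinom(30 * 5, 2, 0.4), 30, 5)
  geno <- toyGeno(d, pos = pos)
  genes <- data.frame(gene = "g1", chrom = "1", start = 2e6, end = 2.05e6)
  expr <- matrix(rnorm(30), 30, 1, dimnames = list(paste0("s", 1:30), "g1"))
  res <- cisEqtl(expr, geno, genes)
  expect_setequal(res$ID, c("v1", "v3", "v5"))   # v2 and v4 are 1 bp too far
  expect_true(all(c("P", "q") %in% names(res)))

  # gene with no cis variants is skipped with a note
  genes2 <- rbind(genes, data.frame(gene = "g2", chrom = "2", start = 1,
                                    end = 100))
  res2 <- cisEqtl(expr, geno, genes2)
  expect_identical(attr(res2, "skippedGenes"), "g2")
})

test_that("planted cis effects are recovered within +/- 2 SE", {
  set.seed(97)
  n <- 300
  hits <- 0
  for (rep in 1:20) {
    g <- rbinom(n, 2, 0.3)
    y <- 0.5 * g + rnorm(n)
    geno <- toyGeno(matrix(g, n, 1), pos = 5e5)
    expr <- matrix(y, n, 1, dimnames = list(paste0("s", 1:n), "g1"))
    genes <- data.frame(gene = "g1", chrom = "1", start = 4e5, end = 4.5e5)
    res <- cisEqtl(expr, geno, genes)
    if (abs(res$BETA - 0.5) <= 2 * res$SE) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("constant covariates are dropped with a warning", {
  set.seed(98)
  n <- 40
  geno <- toyGeno(matrix(rbinom(n, 2, 0.4), n, 1))
  cov <- data.frame(age = rnorm(n, 75), flat = 1, row.names = paste0("s", 1:n))
  expect_warning(tab <- qtGwas(setNames(rnorm(n), paste0("s", 1:n)), geno,
                               cov = cov),
                 "constant covariate")
  expect_false(is.na(tab$BETA))
})
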