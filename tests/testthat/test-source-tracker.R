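test_that("the full conditional equals a straight-line recomputation", {
  set.seed(21)
  for (rep in 1:10) {
    V <- sample(1:3, 1); T <- sample(2:5, 1)
    m <- matrix(rpois(V * T, 10), V, T,
                dimnames = list(paste0("E", 1:V), paste0("t", 1:T)))
    src <- toySourceSet(m)
    n <- matrix(rpois((V + 1) * T, 2), V + 1, T)
    cfg <- gibbsConfig(alpha1 = runif(1, 1e-3, 1), alpha2 = runif(1, 1e-3,
                                                                  1),
                       beta = runif(1, 0.5, 20))
    t0 <- sample(T, 1)
    got <- gibbsConditional(t0, n, src, cfg)
    ref <- refConditional(t0, n, m, cfg@alpha1, cfg@alpha2, cfg@beta)
    expect_equal(unname(got), ref, tolerance = 1e-12)
    # trainingOnly switch honored
    cfgT <- gibbsConfig(alpha1 = cfg@alpha1, alpha2 = cfg@alpha2,
                        beta = cfg@beta, trainingOnly = TRUE)
    expect_equal(unname(gibbsConditional(t0, n, src, cfgT)),
                 refConditional(t0, n, m, cfg@alpha1, cfg@alpha2,
                                cfg@beta, trainingOnly = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("the conditional is symmetric for identical sources and favors Unknown for unseen taxa", {
  m <- matrix(c(5, 3, 5, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("t1", "t2")))
  src <- toySourceSet(m)
  n <- matrix(0, 3, 2)
  p <- gibbsConditional(1, n, src, gibbsConfig())
  expect_equal(p[["A"]], p[["B"]], tolerance = 1e-12)

  # taxon untrained everywhere, alpha2 >> alpha1: Unknown dominates
  m2 <- matrix(c(50, 0, 60, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("t1", "t2")))
  p2 <- gibbsConditional(2, matrix(0, 3, 2), toySourceSet(m2),
                         gibbsConfig(alpha1 = 1e-4, alpha2 = 0.5))
  expect_equal(names(which.max(p2)), "Unknown")
})

test_that("exact enumeration is exchangeable and symmetric", {
  m <- matrix(c(4, 2, 1, 4, 2, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("t1", "t2", "t3")))
  src <- toySourceSet(m)
  cfg <- gibbsConfig(alpha2 = 0.01)
  # N = 1: identical sources split the known mass evenly
  p1 <- exactPosterior(c(t1 = 1, t2 = 0, t3 = 0), src, cfg)
  expect_equal(p1[["A"]], p1[["B"]], tolerance = 1e-12)
  expect_equal(sum(p1), 1, tolerance = 1e-12)

  # order invariance: permuting the shared taxon index leaves the
  # result unchanged (enumeration weights are exchangeable)
  perm <- c(3, 1, 2)
  mP <- m[, perm]; colnames(mP) <- colnames(m)[perm]
  srcP <- toySourceSet(mP)
  sink <- c(t1 = 2, t2 = 1, t3 = 3)
  expect_equal(exactPosterior(sink, src, cfg),
               exactPosterior(sink[perm], srcP, cfg), tolerance = 1e-12)

  expect_error(exactPosterior(stats::setNames(rep(3, 3),
                                              c("t1", "t2", "t3")),
                              src, cfg), "too large")
})

test_that("long-run Gibbs means agree with exact enumeration on a small instance", {
  m <- matrix(c(8, 1, 1, 0, 1, 1, 8, 0), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("t", 1:4)))
  src <- toySourceSet(m)
  sink <- c(t1 = 2, t2 = 1, t3 = 2, t4 = 1)
  cfg <- gibbsConfig(alpha2 = 0.00415, burnIn = 200, restarts = 100,
                     drawsPerRestart = 20)
  est <- fitMixture(sink, src, cfg, seed = 4)
  ex <- exactPosterior(sink, src, cfg)
  expect_lt(max(abs(mixtureProportions(est) - ex)), 0.02)
})

test_that("fitMixture is seeded-deterministic with unit-sum draws and paper defaults", {
  d <- gibbsConfig()
  expect_equal(d@burnIn, 1000L)
  expect_equal(d@restarts, 25L)
  expect_equal(d@alpha2, 0.00415)

  prof <- blockProfiles(2, 10, seed = 2)
  ts <- trainedSources(prof, depth = 500, reps = 2)
  snk <- genSink(c(Env1 = 0.5, Env2 = 0.5), prof, depth = 200, seed = 3)
  cfg <- gibbsConfig(burnIn = 50, restarts = 6)
  a <- fitMixture(snk$table, ts$sources, cfg, seed = 11)
  b <- fitMixture(snk$table, ts$sources, cfg, seed = 11)
  expect_identical(mixtureDraws(a), mixtureDraws(b))
  expect_equal(unname(rowSums(mixtureDraws(a))), rep(1, 6),
               tolerance = 1e-9)
  expect_error(fitMixture(stats::setNames(numeric(ncol(prof)),
                                          colnames(prof)),
                          ts$sources, cfg), "empty sink")
})

test_that("duplicated sources receive statistically indistinguishable mass", {
  prof <- blockProfiles(2, 10, seed = 8)
  profDup <- rbind(prof, Env3 = prof[2, ])
  ts <- trainedSources(profDup, depth = 1000, reps = 3)
  snk <- genSink(c(Env2 = 1), prof, depth = 400, seed = 5)
  est <- fitMixture(snk$table, ts$sources,
                    gibbsConfig(burnIn = 300, restarts = 12), seed = 6)
  mu <- mixtureProportions(est); sd <- mixtureSD(est)
  tol <- 2 * sqrt(sd[["Env2"]]^2 + sd[["Env3"]]^2)
  expect_lt(abs(mu[["Env2"]] - mu[["Env3"]]), max(tol, 0.05))
})

test_that("restart summaries flag bimodal draws and shorten the display ordering", {
  envs <- c("Compost", "Unknown")
  flat <- matrix(rep(c(0.02, 0.98), each = 25), 25, 2,
                 dimnames = list(NULL, envs))
  same <- summarizeRestarts(flat, sdThreshold = 0.15)
  expect_false(isLowConfidence(same))
  expect_equal(unname(mixtureSD(same)), c(0, 0))

  # 23 restarts all-Unknown, 2 all-Compost: low confidence
  bim <- rbind(matrix(rep(c(0.02, 0.98), each = 23), 23, 2),
               matrix(rep(c(0.95, 0.05), each = 2), 2, 2))
  colnames(bim) <- envs
  bimShuf <- bim[c(1, 24, 2:12, 25, 13:23), ]
  est <- summarizeRestarts(bimShuf, sdThreshold = 0.15)
  expect_true(isLowConfidence(est))

  pathLen <- function(d, ord)
    sum(sqrt(rowSums((d[ord[-1], , drop = FALSE] -
                      d[ord[-length(ord)], , drop = FALSE])^2)))
  set.seed(31)
  for (rep in 1:5) {
    d <- matrix(runif(40), 10, 4)
    d <- d / rowSums(d)
    colnames(d) <- paste0("E", 1:4)
    s <- summarizeRestarts(d, sdThreshold = 1)
    expect_lte(pathLen(d, s@drawOrder), pathLen(d, 1:10) + 1e-12)
  }
})

test_that("contamination screening flags sinks with contaminant signal", {
  mk <- function(skin) {
    draws <- matrix(rep(c(skin, 1 - skin), each = 3), 3, 2,
                    dimnames = list(NULL, c("skin", "Unknown")))
    summarizeRestarts(draws, sinkId = paste0("s", skin))
  }
  cc <- contaminationCheck(list(mk(0), mk(0.5)), "skin", threshold = 0.1)
  expect_equal(cc$pass, c(TRUE, FALSE))
  expect_error(contaminationCheck(mk(0), "oral"), "unknown environment")
})
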