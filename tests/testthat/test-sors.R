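test_that("greedy selection equals the exhaustive oracle on a toy grid", {
  g <- toyGrid6()
  X <- toyData(d = 6, N = 30, seed = 5)
  plan <- trainSORS(X, kind = "lr", grid = g)
  chosen <- integer(0)
  for (k in 1:6) {
    expect_equal(planOrder(plan)[k], bruteNext(X, chosen, "lr"))
    chosen <- c(chosen, planOrder(plan)[k])
  }
  # and for ttpcr with a frozen 2-component basis
  plan2 <- trainSORS(X, kind = "ttpcr", n = 2, grid = g)
  basis <- fitPCA(X, 2)
  chosen <- integer(0)
  for (k in 1:6) {
    expect_equal(planOrder(plan2)[k], bruteNext(X, chosen, "ttpcr", basis))
    chosen <- c(chosen, planOrder(plan2)[k])
  }
})

test_that("a duplicated location adds no information once its twin is chosen", {
  g <- toyGrid6()
  X <- toyData(d = 6, N = 25, seed = 6)
  X[4, ] <- X[1, ]  # location 4 duplicates location 1
  plan <- trainSORS(X, kind = "lr", grid = g)
  ord <- planOrder(plan)
  curve <- trainingCurve(plan)
  first <- min(which(ord %in% c(1L, 4L)))
  second <- which(ord == setdiff(c(1L, 4L), ord[first]))
  # marginal improvement when the duplicate is finally added is ~0
  expect_lt(curve[second - 1] - curve[second], 1e-8)
})

test_that("training curve is non-increasing and exact at full observation", {
  d <- cachedFields(30, 321)
  X <- dbValues(d)
  plan <- trainSORS(X, kind = "lr")
  expect_true(all(diff(trainingCurve(plan)) <= 1e-8))
  expect_lt(trainingCurve(plan)[54], 1e-8)
  # order is a permutation and models match their prefixes
  expect_setequal(planOrder(plan), 1:54)
  for (k in c(1, 7, 30)) {
    expect_identical(measuredSubset(plan@models[[k]]),
                     planOrder(plan)[1:k])
  }
})

test_that("plans are invariant to training column order", {
  g <- toyGrid6()
  X <- toyData(d = 6, N = 20, seed = 7)
  p1 <- trainSORS(X, kind = "lr", grid = g)
  set.seed(1)
  p2 <- trainSORS(X[, sample(20)], kind = "lr", grid = g)
  expect_identical(planOrder(p1), planOrder(p2))
  expect_equal(trainingCurve(p1), trainingCurve(p2), tolerance = 1e-9)
})

test_that("plan estimates substitute measured values and match the matrix oracle", {
  g <- toyGrid6()
  X <- toyData(d = 6, N = 20, seed = 8)
  plan <- trainSORS(X, kind = "lr", grid = g)
  ord <- planOrder(plan)
  truth <- X[, 3]
  # full prefix: estimate equals the measured field exactly
  meas <- setNames(truth[ord], ord)
  expect_equal(planEstimate(plan, meas, 6), truth, ignore_attr = TRUE)
  # k = 2 against a hand-applied D s + beta with substitution
  m2 <- plan@models[[2]]
  s <- truth[ord[1:2]]
  oracle <- pmin(pmax(as.numeric(m2@D %*% s + m2@beta), 0), 40)
  oracle[ord[1:2]] <- s
  expect_equal(planEstimate(plan, setNames(s, ord[1:2]), 2), oracle,
               ignore_attr = TRUE)
  # k = 1 returns the model-1 reconstruction overwritten at the tested site
  m1 <- plan@models[[1]]
  s1 <- truth[ord[1]]
  o1 <- pmin(pmax(as.numeric(m1@D %*% s1 + m1@beta), 0), 40)
  o1[ord[1]] <- s1
  expect_equal(planEstimate(plan, setNames(s1, ord[1]), 1), o1,
               ignore_attr = TRUE)
  expect_error(planEstimate(plan, meas, 0), "between 1")
  expect_error(planEstimate(plan, setNames(truth[ord[1:2]], ord[c(1, 3)]), 2),
               "exactly the first")
})

test_that("mean-baseline plan orders locations by descending variance", {
  d <- cachedFields(30, 322)
  X <- dbValues(d)
  plan <- trainSORS(X, kind = "mean")
  v <- apply(X, 1, var)
  expect_identical(planOrder(plan), order(-v, seq_len(54)))
  # reconstruction ignores measurements
  est <- planEstimate(plan, setNames(X[planOrder(plan)[1], 1],
                                     planOrder(plan)[1]), 1,
                      substitute = FALSE)
  expect_equal(est, pmin(pmax(rowMeans(X), 0), 40), ignore_attr = TRUE)
})

test_that("quadrant plan starts at the quadrant centers and grows outward", {
  d <- cachedFields(20, 323)
  g <- vfGrid242()
  plan <- quadrantPlan(dbValues(d), grid = g)
  co <- gridCoords(g)
  first4 <- planOrder(plan)[1:4]
  expect_true(all(abs(co[first4, 1]) == 9 & abs(co[first4, 2]) == 9))
  expect_setequal(planOrder(plan), 1:54)
  # every later location has an earlier within-quadrant neighbor
  ord <- planOrder(plan)
  for (k in 5:54) {
    loc <- ord[k]
    nb <- neighborsOf(g, loc)
    nb <- nb[quadrantOf(g, nb) == quadrantOf(g, loc)]
    expect_true(any(nb %in% ord[1:(k - 1)]))
  }
})

test_that("quadrant growth seeding propagates deviations", {
  d <- cachedFields(20, 323)
  g <- vfGrid242()
  nv <- normativeHill(dbValues(d))
  center <- locationIndex(g, 9, 9)
  nb <- neighborsOf(g, center)
  nb <- nb[quadrantOf(g, nb) == "superotemporal"][1]
  # measured exactly normative -> neighbor starts at its own normative
  det <- setNames(nv[center], center)
  expect_equal(quadrantGrowthSeed(g, det, nv, nb), nv[nb])
  # measured 10 dB below -> neighbor starts 10 below its normative
  det10 <- setNames(nv[center] - 10, center)
  expect_equal(quadrantGrowthSeed(g, det10, nv, nb), nv[nb] - 10)
  # two determined neighbors at -4 and -8 average to -6
  loc <- locationIndex(g, 15, 9)
  nbs <- intersect(neighborsOf(g, loc),
                   which(quadrantOf(g, 1:54) == "superotemporal"))
  det2 <- setNames(nv[nbs[1:2]] + c(-4, -8), nbs[1:2])
  expect_equal(quadrantGrowthSeed(g, det2, nv, loc), nv[loc] - 6)
  expect_error(quadrantGrowthSeed(g, det, nv, center), "unshifted prior")
})

test_that("sequence map labels every location once with the band scheme", {
  d <- cachedFields(20, 324)
  plan <- quadrantPlan(dbValues(d))
  sm <- sequenceMap(plan)
  expect_setequal(sm$rank, 1:54)
  expect_equal(sum(sm$band == "1-4"), 4)
  expect_equal(sum(sm$band == "5-20"), 16)
  expect_equal(sum(sm$band == "21-36"), 16)
  f <- withr::local_tempfile(fileext = ".png")
  plotSequenceMap(plan, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("plan JSON archives restore equivalent predictions", {
  d <- cachedFields(25, 325)
  X <- dbValues(d)
  plan <- trainSORS(X, kind = "ttpcr", n = 4)
  f <- withr::local_tempfile(fileext = ".json")
  planToJSON(plan, f)
  plan2 <- planFromJSON(f)
  expect_identical(planOrder(plan2), planOrder(plan))
  ord <- planOrder(plan)
  meas <- setNames(X[ord[1:5], 2], ord[1:5])
  expect_equal(planEstimate(plan2, meas, 5), planEstimate(plan, meas, 5),
               tolerance = 1e-10)
})
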