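test_that("field tests keep exact trial bookkeeping in batches", {
  tr <- cachedFields(40, 351)
  Xtr <- dbValues(tr)
  plan <- trainSORS(Xtr, kind = "ttpcr", n = 8)
  zcfg <- zestConfig(buildPrior(Xtr))
  truth <- dbValues(cachedFields(5, 352))[, 1]
  res <- runFieldTest(strategyConfig("sors", stopAfter = 36, batchSize = 4),
                      plan, truth, zcfg, seed = 3)
  expect_equal(sum(res$presentations > 0), 36)
  expect_equal(nrow(res$trajectory), 9)        # 36 locations / batch of 4
  expect_equal(res$totalTrials, sum(res$presentations))
  expect_equal(res$totalTrials, nrow(res$log))
  expect_equal(res$trajectory$locations, seq(4, 36, by = 4))
  expect_true(all(diff(res$trajectory$trials) > 0))
  # untested locations carry the reconstruction, tested ones the measurement
  ord <- planOrder(plan)[1:36]
  expect_equal(res$finalEstimate[ord],
               unname(res$measured[as.character(ord)]))
})

test_that("independent testing with the mean model leaves the hill at untested sites", {
  tr <- cachedFields(40, 351)
  Xtr <- dbValues(tr)
  plan <- trainSORS(Xtr, kind = "mean")
  zcfg <- zestConfig(buildPrior(Xtr))
  truth <- dbValues(cachedFields(5, 352))[, 2]
  res <- runFieldTest(strategyConfig("independent", stopAfter = 20),
                      plan, truth, zcfg, seed = 4)
  untested <- setdiff(1:54, planOrder(plan)[1:20])
  expect_equal(res$finalEstimate[untested], rowMeans(Xtr)[untested],
               ignore_attr = TRUE)
})

test_that("a determinized full test recovers the field", {
  tr <- cachedFields(40, 351)
  Xtr <- dbValues(tr)
  plan <- trainSORS(Xtr, kind = "ttpcr", n = 8)
  zcfg <- zestConfig(buildPrior(Xtr))
  truth <- dbValues(cachedFields(5, 352))[, 3]
  res <- runFieldTest(strategyConfig("sors", stopAfter = 54), plan, truth,
                      zcfg, fp = 0, fn = 0, rampHalfwidth = 0, seed = 5)
  expect_lte(max(abs(res$finalEstimate - truth)), 2)
  expect_lte(tail(res$trajectory$rmse, 1), 2)
})

test_that("field tests are bit-reproducible under the seed hierarchy", {
  tr <- cachedFields(40, 351)
  Xtr <- dbValues(tr)
  plan <- quadrantPlan(Xtr)
  zcfg <- zestConfig(buildPrior(Xtr))
  truth <- dbValues(cachedFields(5, 352))[, 4]
  strat <- strategyConfig("quadrant", stopAfter = 36)
  r1 <- runFieldTest(strat, plan, truth, zcfg, seed = 9)
  r2 <- runFieldTest(strat, plan, truth, zcfg, seed = 9)
  expect_identical(r1, r2)
  r3 <- runFieldTest(strat, plan, truth, zcfg, seed = 10)
  expect_false(identical(r1$log, r3$log))
})

test_that("cross-validation partitions eyes without leakage", {
  dat <- cachedFields(20, 353, visitsPerEye = 2)
  strategies <- list(
    ttpcr = list(strategy = strategyConfig("sors", stopAfter = 36),
                 kind = "ttpcr", n = 4),
    indep = list(strategy = strategyConfig("independent", stopAfter = 54),
                 kind = "mean")
  )
  ev <- crossValidate(dat, strategies, scheme = "small", seed = 2,
                      maxTestFieldsPerFold = 2)
  # fold test sets partition the eyes
  allEyes <- unique(eyeIds(dat))
  expect_setequal(unlist(ev$folds), allEyes)
  expect_equal(anyDuplicated(unlist(ev$folds)), 0L)
  # no eye is both trained and tested within a fold (small: train = fold f)
  for (f in unique(ev$fields$fold)) {
    tested <- ev$fields$eye_id[ev$fields$fold == f]
    expect_length(intersect(tested, ev$folds[[f]]), 0)
  }
  expect_setequal(unique(ev$fields$strategy), c("ttpcr", "indep"))
  expect_true(all(c("locations", "trials", "rmse") %in%
                  names(ev$checkpoints)))
  # reproducible; different seed reshuffles folds but keeps the schema
  ev2 <- crossValidate(dat, strategies, scheme = "small", seed = 2,
                       maxTestFieldsPerFold = 2)
  expect_identical(ev$fields, ev2$fields)
  ev3 <- crossValidate(dat, strategies["indep"], scheme = "small", seed = 3,
                       maxTestFieldsPerFold = 2)
  expect_false(identical(ev$folds, ev3$folds))
  expect_identical(names(ev3$fields), names(ev$fields))
  expect_error(crossValidate(dbValues(dat), strategies), "VFDataset")
})

test_that("severity stratification uses the staging cutoffs", {
  df <- data.frame(strategy = "s",
                   md = c(-5.9, -6, -11.9, -12, -20, 1),
                   rmse = 1:6, trials = 1:6)
  out <- severityStratify(df)
  expect_setequal(out$severity, c("mild", "moderate", "severe"))
  expect_equal(out$n[out$severity == "mild"], 2)      # -5.9 and 1
  expect_equal(out$n[out$severity == "moderate"], 2)  # -6 and -11.9
  expect_equal(out$n[out$severity == "severe"], 2)    # -12 and -20
  # an all-normal cohort lands entirely in the mild stratum
  dn <- generateFields(
    generatorConfig(nEyes = 8, visitsPerEye = 1,
                    severityMix = c(normal = 1, mild = 0, moderate = 0,
                                    severe = 0)), seed = 44)
  g <- vfGrid242()
  h <- normativeHill(dn)
  md <- apply(dbValues(dn), 2, meanDeviation, normative = h, grid = g)
  expect_true(all(severityClass(md) == "mild"))
})

test_that("fold sizes follow the 20/80 and 90/10 schemes", {
  dat <- cachedFields(20, 353, visitsPerEye = 2)
  eyes <- unique(eyeIds(dat))
  strategies <- list(indep = list(strategy = strategyConfig("independent",
                                                            stopAfter = 4),
                                  kind = "mean"))
  small <- crossValidate(dat, strategies, scheme = "small", seed = 1,
                         maxTestFieldsPerFold = 1)
  expect_length(small$folds, 5)
  expect_true(all(lengths(small$folds) == 4))  # 20% of 20 eyes train
  large <- crossValidate(dat, strategies, scheme = "large", seed = 1,
                         maxTestFieldsPerFold = 1)
  expect_length(large$folds, 10)
  expect_true(all(lengths(large$folds) == 2))  # folds of 10%; train on 90%
})
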