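makeLodSet <- function() {
  # 5 samples; mA has 2/5 (40%) below LOD, mB exactly 1/5 (20%), mC none
  v <- cbind(mA = c(0.5, 0.6, 2, 3, 4),
             mB = c(0.5, 2, 3, 4, 5),
             mC = c(2, 3, 4, 5, 6))
  rownames(v) <- paste0("s", 1:5)
  tinySet(v, lod = c(mA = 1, mB = 1, mC = 1))
}

test_that("LOD filter applies the strict > 20% rule without imputation", {
  res <- filterByLOD(makeLodSet())
  expect_equal(res$report$dropped_ids, "mA")
  expect_equal(res$report$n_retained, 2L)
  expect_equal(res$report$n_input_metabolites, 3L)
  v <- concentrations(res$mset)
  expect_equal(colnames(v), c("mB", "mC"))
  expect_equal(v[1, "mB"], 0.5)        # below-LOD value of a kept metabolite survives

  # identity when everything is above the limit
  clean <- tinySet(matrix(5, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b"))),
                   lod = c(a = 1, b = 1))
  res2 <- filterByLOD(clean)
  expect_equal(length(res2$report$dropped_ids), 0L)
  expect_equal(concentrations(res2$mset), concentrations(clean))

  # idempotence
  twice <- filterByLOD(res$mset)
  expect_equal(concentrations(twice$mset), concentrations(res$mset))
  expect_equal(length(twice$report$dropped_ids), 0L)

  # missing values count as not detected
  vna <- cbind(m = c(NA, NA, 5, 5, 5))
  rownames(vna) <- paste0("s", 1:5)
  resna <- filterByLOD(tinySet(vna, lod = c(m = 1)))
  expect_equal(resna$report$dropped_ids, "m")

  noLod <- tinySet(matrix(1, 2, 1, dimnames = list(c("s1", "s2"), "m")))
  expect_error(filterByLOD(noLod), class = "MissingLODError")
})

bridgedSet <- function(v2 = 8) {
  # bridge sample BR measured in both batches; metabolite m: 10 in batch 1,
  # 20 in batch 2 (factor 1/2); one ordinary sample per batch
  v <- rbind(BR_b1 = c(m = 10, n = 4),
             BR_b2 = c(m = 20, n = 8),
             s1    = c(m = 6,  n = 3),
             s2    = c(m = v2, n = 10))
  tinySet(v, batch = c(1L, 2L, 1L, 2L),
          bridge = c(TRUE, TRUE, FALSE, FALSE),
          sample_id = c("BR", "BR", "s1", "s2"))
}

test_that("bridge normalization rescales non-reference batches by the bridge ratio", {
  res <- bridgeNormalize(bridgedSet())
  v <- concentrations(res$mset)
  expect_equal(unname(v["s2", "m"]), 4)          # 8 * 10/20
  expect_equal(unname(v["s2", "n"]), 5)          # 10 * 4/8
  expect_equal(unname(v["s1", ]), c(6, 3))       # reference batch untouched
  expect_false(any(c("BR_b1", "BR_b2") %in% rownames(v)))  # used runs removed
  expect_equal(res$report$bridge_sample, "BR")
  expect_equal(unname(res$report$per_batch_factors[["2"]]), c(0.5, 0.5))

  # single-batch table is untouched
  single <- tinySet(matrix(1:4 + 0, 2, 2,
                           dimnames = list(c("s1", "s2"), c("a", "b"))))
  res1 <- bridgeNormalize(single)
  expect_equal(concentrations(res1$mset), concentrations(single))

  # all factors 1 => identity on the retained samples
  v <- rbind(BR_b1 = c(m = 10), BR_b2 = c(m = 10), s1 = c(m = 6), s2 = c(m = 8))
  same <- tinySet(v, batch = c(1L, 2L, 1L, 2L), bridge = c(TRUE, TRUE, FALSE, FALSE),
                  sample_id = c("BR", "BR", "s1", "s2"))
  resI <- bridgeNormalize(same)
  expect_equal(unname(concentrations(resI$mset)[, "m"]), c(6, 8))

  # degenerate bridge value
  vz <- rbind(BR_b1 = c(m = 10), BR_b2 = c(m = 0), s1 = c(m = 6), s2 = c(m = 8))
  zset <- tinySet(vz, batch = c(1L, 2L, 1L, 2L), bridge = c(TRUE, TRUE, FALSE, FALSE),
                  sample_id = c("BR", "BR", "s1", "s2"))
  expect_error(bridgeNormalize(zset), class = "DegenerateBridgeError")
})

test_that("row normalization equalizes totals while restoring the grand mean", {
  one <- tinySet(matrix(c(2, 3, 5), 1, 3,
                        dimnames = list("s1", c("a", "b", "c"))))
  resq <- rowNormalize(one)
  expect_equal(unname(concentrations(resq$mset)[1, ]), c(2, 3, 5))  # fixed point

  two <- tinySet(matrix(c(1, 3, 1, 3), 2, 2,
                        dimnames = list(c("s1", "s2"), c("a", "b"))))
  res2 <- rowNormalize(two)
  expect_equal(unname(concentrations(res2$mset)), matrix(2, 2, 2))

  set.seed(1)
  big <- tinySet(matrix(rexp(60) + 0.1, 10, 6,
                        dimnames = list(paste0("s", 1:10), paste0("m", 1:6))))
  res3 <- rowNormalize(big)
  totals <- rowSums(concentrations(res3$mset))
  expect_lt(sd(totals) / mean(totals), 1e-12)

  zero <- tinySet(matrix(0, 1, 2, dimnames = list("s1", c("a", "b"))))
  expect_error(rowNormalize(zero), class = "DegenerateSampleError")
})

test_that("autoscaling centers, scales and inverts exactly", {
  v <- matrix(c(1, 2, 3, 10, 20, 60), 3, 2,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  sc <- autoscale(v)
  expect_equal(unname(sc$X[, "a"]), c(-1, 0, 1))      # sample sd of 1,2,3 is 1
  expect_true(all(abs(colMeans(sc$X)) < 1e-12))
  expect_equal(unname(apply(sc$X, 2, sd)), c(1, 1))
  back <- inverseAutoscale(sc$X, sc)
  expect_lt(max(abs(back - v) / v), 1e-10)

  vc <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  rownames(vc) <- paste0("s", 1:3)
  err <- tryCatch(autoscale(vc), error = identity)
  expect_s3_class(err, "ConstantMetaboliteError")
  expect_match(conditionMessage(err), "a")            # names the metabolite
})

test_that("the full chain composes deterministically in its fixed order", {
  sim <- simulateMetabolome(seed = 11)
  p1 <- preprocessPipeline(sim$mset)
  p2 <- preprocessPipeline(sim$mset)
  expect_identical(p1$X, p2$X)
  expect_named(p1$reports, c("lod", "bridge", "row", "scale"))
  totals <- rowSums(concentrations(p1$mset))
  expect_lt(sd(totals) / mean(totals), 1e-12)
  # collapsed: one measurement per sample
  expect_false(anyDuplicated(studyDesign(p1$mset)$sample_id) > 0)
})
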