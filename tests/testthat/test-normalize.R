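test_that("loess surface of a constant plate is that constant", {
  out <- correctSpatialBias(flatGrid(500))
  f <- out$fit@fitted
  expect_equal(unname(f[!is.na(f)]), rep(500, 384), tolerance = 1e-9)
  expect_equal(unname(out$corrected), unname(flatGrid(500)), tolerance = 1e-9)
  expect_error(correctSpatialBias(flatGrid(0)), "degenerate")
  expect_error(correctSpatialBias(flatGrid(1), span = 0), "span")
})

test_that("an injected linear gradient is removed on a noise-free plate", {
  g <- flatGrid(1000, spatialField(gradientRow = 0.2))
  out <- correctSpatialBias(g)
  rng <- range(out$corrected)
  expect_lt(diff(rng) / mean(out$corrected), 0.01)
  # median preservation: a linear field is reproduced exactly by the
  # degree-1 local fit, so corrected values equal the rescaling target
  expect_equal(median(out$corrected),
               median(out$fit@fitted, na.rm = TRUE), tolerance = 1e-6)
})

test_that("a single 10x outlier barely moves the other wells", {
  g0 <- flatGrid(800, spatialField(gradientRow = 0.1, gradientCol = 0.05))
  g1 <- g0
  g1[8, 12] <- g0[8, 12] * 10
  c0 <- correctSpatialBias(g0)$corrected
  c1 <- correctSpatialBias(g1)$corrected
  rel <- abs(c1[-(8 + 16 * 11)] - c0[-(8 + 16 * 11)]) / c0[-(8 + 16 * 11)]
  expect_lt(max(rel), 0.01)
  # the outlier's final robustness weight is ~0
  expect_lt(correctSpatialBias(g1)$fit@weights[8, 12], 0.01)
})

test_that("control normalization gives log2 ratios with a zero centre", {
  sc <- noiseFreeScreen(nDrugs = 4, models = "2D7d", seed = 13)
  scr <- assembleScreen(sc$plates, sc$layouts)
  w <- wells(scr)
  w$corrected <- w$raw
  scr <- screen3D:::ScreenData(w, log = scr@log)
  nrm <- normalizeToControls(scr)
  wn <- wells(nrm)
  neg <- wn$role == "negative_control"
  # noise off: all controls equal the centre -> loess-log 0
  expect_equal(wn$loess_log[neg], rep(0, sum(neg)), tolerance = 1e-12)

  # doubling and halving map to +1 / -1; inverse map recovers percent
  m <- median(wn$corrected[neg])
  w2 <- wn
  w2$corrected[1] <- 2 * m
  w2$corrected[2] <- 0.5 * m
  n2 <- wells(normalizeToControls(screen3D:::ScreenData(w2)))
  expect_equal(n2$loess_log[1:2], c(1, -1))
  expect_equal(100 * 2^n2$loess_log[2], 50)

  # non-positive wells floored and flagged
  w3 <- wn
  w3$corrected[3] <- 0
  n3 <- wells(normalizeToControls(screen3D:::ScreenData(w3)))
  expect_true(n3$floored[3])
  expect_equal(n3$ctrl_ratio[3], 1e-3)

  # no negative controls -> hard error naming the plate
  w4 <- wn[wn$role != "negative_control", ]
  expect_error(normalizeToControls(screen3D:::ScreenData(w4)),
               wn$barcode[1])
})

test_that("plate-median centering zeroes every plate's sample median", {
  tr <- makeTruth(20, models = c("2D7d", "MG7d"), seed = 17, noiseCv = 0.1)
  lay <- screenLayouts(tr, bioReps = 2)
  nrm <- normalizeScreen(assembleScreen(simulateScreen(tr, lay, seed = 18), lay))
  w <- wells(nrm)
  meds <- tapply(w$centered[w$role == "sample"], w$barcode[w$role == "sample"], median)
  expect_true(all(abs(meds) < 1e-9))
})

test_that("correction halves the spread of control loess-logs on biased plates", {
  # scaled-down version of the bias-removal property (20 plates here;
  # the full 100-plate version runs in the acceptance suite)
  set.seed(99)
  ratios <- replicate(20, {
    g <- runif(1, 0.1, 0.3)
    tr <- makeTruth(80, models = "2D7d", seed = sample.int(1e6, 1),
                    gradientRow = g, gradientCol = g / 2, edgeEffect = 1,
                    noiseCv = 0.05)
    lay <- screenLayouts(tr, bioReps = 1)
    pl <- simulateScreen(tr, lay, seed = sample.int(1e6, 1))
    scr <- assembleScreen(pl, lay)
    nrm <- normalizeScreen(scr)
    w <- wells(nrm)
    neg <- w$role == "negative_control"
    pre <- log2(w$raw[neg] / median(w$raw[neg]))
    c(pre = stats::sd(pre), post = stats::sd(w$loess_log[neg]))
  })
  expect_lt(mean(ratios["post", ]) / mean(ratios["pre", ]), 0.5)
})

test_that("replicate aggregation solves the least-squares system", {
  # constant cells, balanced design -> estimates equal the constants
  sc <- noiseFreeScreen(nDrugs = 3, models = "2D7d", seed = 23, bioReps = 3)
  nrm <- normalizeScreen(assembleScreen(sc$plates, sc$layouts), correct = FALSE)
  agg <- aggregateReplicates(nrm)
  w <- wells(nrm)
  smp <- w[w$role == "sample", ]
  for (i in seq_len(nrow(agg))) {
    v <- smp$loess_log[smp$drug == agg$drug[i] &
                       smp$concentration_uM == agg$concentration_uM[i]]
    expect_equal(agg$estimate[i], mean(v), tolerance = 1e-9)
  }

  # unbalanced toy vs explicit normal equations (independent oracle)
  w2 <- smp[smp$drug %in% c("drug001", "drug002") &
            smp$concentration_uM %in% c(0.02, 20), ]
  w2 <- w2[order(w2$drug, w2$concentration_uM, w2$bio_rep), ]
  set.seed(1)
  w2$loess_log <- rnorm(nrow(w2))
  w2 <- w2[-2, ]  # break the balance
  scr2 <- screen3D:::ScreenData(w2)
  agg2 <- aggregateReplicates(scr2)
  # oracle: X = [cell dummies | sum-coded replicate], solve normal equations
  cell <- factor(paste(w2$drug, w2$concentration_uM))
  rep_ <- factor(w2$bio_rep)
  Xc <- sapply(levels(cell), function(l) as.numeric(cell == l))
  S <- stats::contr.sum(nlevels(rep_))
  Xr <- S[as.integer(rep_), , drop = FALSE]
  X <- cbind(Xc, Xr)
  beta <- solve(t(X) %*% X, t(X) %*% w2$loess_log)
  ord <- match(paste(agg2$drug, agg2$concentration_uM), levels(cell))
  expect_equal(agg2$estimate, beta[ord], tolerance = 1e-9,
               ignore_attr = TRUE)

  # a replicate with no overlap is a rank-deficiency error naming the block
  w3 <- smp[smp$bio_rep %in% 1:2, ]
  w3 <- w3[(w3$bio_rep == 1) == (w3$drug == "drug001"), ]
  expect_error(aggregateReplicates(screen3D:::ScreenData(w3)),
               "rank-deficient")
})

test_that("the normalization pipeline is a pure function of its inputs", {
  tr <- makeTruth(10, models = "2D7d", seed = 44, noiseCv = 0.08)
  lay <- screenLayouts(tr, bioReps = 1)
  scr <- assembleScreen(simulateScreen(tr, lay, seed = 45), lay)
  n1 <- normalizeScreen(scr)
  n2 <- normalizeScreen(scr)
  expect_identical(wells(n1), wells(n2))
})
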