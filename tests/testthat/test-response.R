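makeAgg <- function(linear, conc = c(0.02, 0.2, 2, 20), model = "2D7d",
                    library = "lib80", drug = "d1") {
  data.frame(drug = drug, model = model, library = library,
             concentration_uM = conc, estimate = log2(linear))
}

test_that("percent-of-lowest profiles follow the library baseline rule", {
  p <- percentOfLowest(makeAgg(c(100, 100, 80, 50) / 100))
  expect_equal(p$percent, c(100, 100, 80, 50))
  # all concentrations equal -> 100% everywhere
  expect_equal(percentOfLowest(makeAgg(rep(0.7, 4)))$percent, rep(100, 4))
  # lib22: baseline is the mean of the two lowest
  p22 <- percentOfLowest(makeAgg(c(90, 110, 70, 55, 40, 30, 25) / 100,
                                 conc = 20 / 10^(6:0), library = "lib22"))
  expect_equal(p22$percent[4], 55)
  expect_equal(mean(p22$percent[1:2]), 100)
  # scale invariance: a constant multiplier cancels
  p2 <- percentOfLowest(makeAgg(3.7 * c(1, 1, 0.8, 0.5)))
  expect_equal(p2$percent, p$percent)
  # percent of control is the anti-logged estimate
  expect_equal(p$pctControl, c(100, 100, 80, 50))
  expect_error(percentOfLowest(makeAgg(0.5, conc = 2)), "fewer than 2")
})

test_that("the activity filter is strict at the 70% boundary", {
  models <- c("2D7d", "MG7d")
  prof <- do.call(rbind, lapply(models, function(m) rbind(
    makeAgg(c(1, 1, 1, 0.699)[c(1:4)], model = m, drug = "hit"),
    makeAgg(c(1, 1, 1, 0.700), model = m, drug = "edge"),
    makeAgg(c(1, 1, 1, 0.95), model = m, drug = "dud"))))
  prof <- percentOfLowest(prof)
  prof$pctControl[prof$drug == "hit" & prof$model == "MG7d"][4] <- 69.9
  prof$pctControl[prof$drug == "hit" & prof$model == "2D7d"][4] <- 75
  prof$pctControl[prof$drug == "edge"] <- pmax(prof$pctControl[prof$drug == "edge"], 70)
  act <- selectActiveDrugs(prof, models = models)
  expect_identical(as.character(act), "hit")   # 69.9% in one model only
  det <- attr(act, "details")
  expect_false(det$active[det$drug == "edge"]) # exactly 70.0% is not active

  # lowering the threshold never removes an active drug
  for (th in c(25, 20, 10, 5)) {
    act2 <- selectActiveDrugs(prof, threshold = th, models = models)
    expect_true(all(act %in% act2))
    act <- act2
  }

  # a drug missing a model arm is excluded with a warning
  prof2 <- prof[!(prof$drug == "dud" & prof$model == "MG7d"), ]
  expect_warning(a3 <- selectActiveDrugs(prof2, models = models), "dud")
  expect_false("dud" %in% a3)
  expect_error(selectActiveDrugs(prof2, models = models, strict = TRUE))
})

test_that("noise-free screens recover exactly the truth-active drugs", {
  sc <- noiseFreeScreen(nDrugs = 40, models = screenModels(), seed = 77,
                        modelSd = 0.4)
  nrm <- normalizeScreen(assembleScreen(sc$plates, sc$layouts), correct = FALSE)
  prof <- percentOfLowest(aggregateReplicates(nrm))
  act <- selectActiveDrugs(prof)
  td <- truthDrugs(sc$truth)
  lay <- sc$layouts
  truthActive <- sort(unique(unlist(lapply(seq_len(nrow(td)), function(i) {
    cc <- sort(unique(lay$concentration_uM[lay$role == "sample" &
                                           lay$drug == td$drug[i]]))
    v <- hillViability(cc, td$e0[i], td$emax[i], td$ec50[i], td$h[i])
    if (min(v) < 0.7) td$drug[i] else NULL
  }))))
  expect_identical(as.character(act), truthActive)
})

test_that("concentration bins average and test against 2D correctly", {
  # identical per-drug values in all models -> t = 0, p = 1
  base <- do.call(rbind, lapply(c("2D7d", "MG7d"), function(m)
    do.call(rbind, lapply(sprintf("d%d", 1:5), function(d)
      makeAgg(c(1, 0.9, 0.8, 0.5 + 0.05 * as.integer(sub("d", "", d))),
              model = m, drug = d)))))
  prof <- percentOfLowest(base)
  res <- averageByConcentrationBin(prof, reference = "2D7d")
  mg <- res[res$model == "MG7d", ]
  expect_equal(mg$p, rep(1, 4), tolerance = 1e-12)
  twoD <- res[res$model == "2D7d", ]
  expect_equal(mg$mean, twoD$mean)
  expect_true(all(is.na(twoD$p)))

  # high-bin Welch p against the closed form on 3 + 3 values
  a <- c(70, 80, 90); b <- c(50, 60, 70)
  seH <- sqrt(stats::var(a) / 3 + stats::var(b) / 3)
  tHand <- (mean(a) - mean(b)) / seH          # 2.4494897...
  dfHand <- seH^4 / ((stats::var(a) / 3)^2 / 2 + (stats::var(b) / 3)^2 / 2)
  pHand <- 2 * (1 - stats::pt(tHand, dfHand))
  prof2 <- do.call(rbind, lapply(1:3, function(i) rbind(
    makeAgg(c(1, 1, 1, a[i] / 100), model = "MG7d", drug = sprintf("d%d", i)),
    makeAgg(c(1, 1, 1, b[i] / 100), model = "2D7d", drug = sprintf("d%d", i)))))
  res2 <- averageByConcentrationBin(percentOfLowest(prof2), reference = "2D7d")
  high <- res2[res2$model == "MG7d" & res2$bin == "high", ]
  expect_equal(high$mean, mean(a))
  expect_equal(high$p, pHand, tolerance = 1e-12)
  expect_equal(res2$mean[res2$model == "2D7d" & res2$bin == "high"], mean(b))

  # star coding thresholds
  expect_identical(screen3D:::starCode(c(0.04, 0.009, 5e-4, 0.2, NA)),
                   c("*", "**", "***", "", ""))
})

test_that("growth rates reproduce the configured model scales", {
  expect_equal(growthRate(1000, 10, reference = 100)$percentOf2D, 100)
  expect_equal(growthRate(2000, 10, reference = 100)$percentOf2D, 200)
  expect_error(growthRate(-1, 10), "positive")

  # noise-free screen: measured MG/PH rate ratio = 1.86 * 7.2 = 13.392
  sc <- noiseFreeScreen(nDrugs = 4, models = c("2D7d", "MG7d", "PH7d"),
                        seed = 55)
  w <- wells(assembleScreen(sc$plates, sc$layouts))
  neg <- w[w$role == "negative_control", ]
  mt <- truthModels(sc$truth)
  ep <- tapply(neg$raw, neg$model, mean)
  rates <- growthRate(ep, mt$cells_plated[match(names(ep), mt$model)])
  ratio <- rates$rate[names(ep) == "MG7d"] / rates$rate[names(ep) == "PH7d"]
  expect_equal(ratio, 13.392, tolerance = 1e-9)
})
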