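erpEpochs <- function(waves, fs = 500, preCue = 100) {
  # waves: list of trials x samples matrices, one entry per condition label
  ntr <- sum(vapply(waves, nrow, integer(1)))
  n <- ncol(waves[[1L]])
  mon <- roiMontage()
  d <- array(0, dim = c(ntr, 10, n))
  i <- 0L
  cond <- character()
  for (cc in names(waves)) for (r in seq_len(nrow(waves[[cc]]))) {
    i <- i + 1L
    for (ch in 1:10) d[i, ch, ] <- waves[[cc]][r, ]
    cond <- c(cond, cc)
  }
  time <- seq(-preCue, by = 1000 / fs, length.out = n)
  EpochSet(d, fs, time, 0,
           data.frame(subject = 1L, condition = cond, kept = TRUE), mon)
}

test_that("ROI averaging equals the brute-force double loop", {
  set.seed(4)
  cfg <- scaledSimConfig(seed = 4, nSubjects = 1, trialsPerCondition = 4)
  ep <- generateSubject(cfg, 1)
  wf <- averageErp(ep, "leftPosterior", "trained")
  idx <- match(posteriorGroups()$leftPosterior, channelLabels(montage(ep)))
  sel <- which(trialInfo(ep)$condition == "trained")
  manual <- rep(0, length(epochTime(ep)))
  for (tr in sel) for (ch in idx)
    manual <- manual + epochData(ep)[tr, ch, ]
  manual <- manual / (length(sel) * length(idx))
  expect_equal(wf$amplitude, manual, tolerance = 1e-12)
  # single trial: the waveform is that trial's group mean
  one <- subsetTrials(ep, sel[1L])
  expect_equal(averageErp(one, "leftPosterior")$amplitude,
               colMeans(epochData(one)[1, idx, ]), tolerance = 1e-12)
  # two opposite trials cancel
  w <- epochData(one)[1, 1, ]
  ep2 <- erpEpochs(list(trained = rbind(w, -w)))
  expect_lt(max(abs(averageErp(ep2, "leftPosterior")$amplitude)), 1e-12)
  expect_error(averageErp(ep, "leftPosterior", "nope"), "no trials")
})

test_that("grand-average peak search honours window, ties and flatness", {
  fs <- 500
  t <- seq(-100, 400, by = 2)
  wf <- data.frame(time_ms = t, amplitude = 0)
  wf$amplitude[t == 100] <- 3
  wf$amplitude[t == 120] <- 3          # tie: earlier one wins
  expect_equal(findGrandPeak(wf, c(70, 150), targetTime = 0), 100)
  # exhaustive argmax oracle on a noisy waveform
  set.seed(6)
  wf2 <- data.frame(time_ms = t, amplitude = rnorm(length(t)))
  idx <- which(t >= 70 & t <= 150)
  expect_equal(findGrandPeak(wf2, c(70, 150), 0),
               t[idx[which.max(wf2$amplitude[idx])]])
  flat <- data.frame(time_ms = t, amplitude = 1)
  expect_warning(mid <- findGrandPeak(flat, c(70, 150), 0), "flat")
  expect_equal(mid, 110)
  # noise-free generated P1 peaks at the injected latency
  ep <- generateSubject(p1OnlyConfig(), 1)
  g <- averageErp(ep, "leftPosterior")
  expect_lte(abs(findGrandPeak(g, c(70, 150), targetTime(ep)) - 115), 2)
})

test_that("window amplitude matches analytic and brute-force means", {
  t <- seq(-100, 400, by = 2)
  const <- matrix(4, 1, length(t))
  ep <- erpEpochs(list(trained = const))
  expect_equal(windowAmplitude(ep, "leftPosterior", "trained",
                               center = 110, width = 30), 4)
  # symmetric triangle spanning exactly the window: mean is half the height
  tri <- pmax(0, 1 - abs(t - 110) / 16)
  ep2 <- erpEpochs(list(trained = matrix(tri, 1)))
  expect_equal(windowAmplitude(ep2, "leftPosterior", "trained",
                               center = 110, width = 32),
               0.5, tolerance = 0.08)
  # brute-force oracle on arbitrary data
  set.seed(8)
  arb <- matrix(rnorm(length(t)), 1)
  ep3 <- erpEpochs(list(trained = arb))
  idx <- which(t >= 95 & t <= 125)
  expect_equal(windowAmplitude(ep3, "leftPosterior", "trained", 110, 30),
               mean(arb[idx]), tolerance = 1e-12)
  expect_error(windowAmplitude(ep3, "leftPosterior", "trained", 395, 30),
               "past the epoch")
})

test_that("single-trial peaks find the largest interior local maximum", {
  t <- seq(-100, 400, by = 2)
  ramp <- matrix(seq_along(t), 1)              # monotone: no interior maximum
  two <- rep(0, length(t))
  two[t == 90] <- 3                            # smaller bump first
  two[t == 130] <- 5                           # larger bump later
  tab <- singleTrialPeaks(erpEpochs(list(trained = rbind(ramp, two))),
                          "leftPosterior", c(70, 150))
  expect_false(tab$detected[1L])
  expect_true(is.na(tab$amplitude[1L]))
  expect_true(tab$detected[2L])
  expect_equal(tab$latency_ms[2L], 130)
  expect_equal(tab$amplitude[2L], 5)
  # exhaustive local-maxima oracle on random trials
  set.seed(9)
  rnd <- matrix(rnorm(5 * length(t)), 5)
  tab2 <- singleTrialPeaks(erpEpochs(list(trained = rnd)), "leftPosterior",
                           c(70, 150))
  idx <- which(t >= 70 & t <= 150)
  for (r in 1:5) {
    v <- rnd[r, ]
    cand <- idx[idx > 1 & idx < length(t)]
    cand <- cand[v[cand] > v[cand - 1] & v[cand] > v[cand + 1] &
                   t[cand] > 70 & t[cand] < 150]
    if (length(cand)) {
      best <- cand[which.max(v[cand])]
      expect_equal(tab2$latency_ms[r], t[best])
      expect_equal(tab2$amplitude[r], v[best])
    } else expect_false(tab2$detected[r])
  }
})

test_that("latency jitter makes the average peak underestimate single-trial peaks", {
  t <- seq(-100, 400, by = 2)
  set.seed(11)
  lats <- 110 + sample(-20:20, 12, replace = TRUE)
  waves <- t(vapply(lats, function(l) exp(-(t - l)^2 / (2 * 12^2)),
                    numeric(length(t))))
  ep <- erpEpochs(list(trained = waves))
  tab <- singleTrialPeaks(ep, "leftPosterior", c(70, 150))
  avg <- averageErp(ep, "leftPosterior")
  pk <- max(avg$amplitude[t >= 70 & t <= 150])
  expect_gte(mean(tab$amplitude[tab$detected]), pk)
})
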