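toneEpochs <- function(freq, fs = 500, dur = 4, amp = 1, nch = 10) {
  n <- dur * fs
  t <- seq_len(n) / fs
  d <- aperm(array(amp * sin(2 * pi * freq * t), dim = c(n, 1, nch)),
             c(2, 3, 1))
  time <- seq(-1000, by = 1000 / fs, length.out = n)
  EpochSet(d, fs, time, 1017,
           data.frame(subject = 1, condition = "trained", kept = TRUE),
           roiMontage())
}

test_that("wavelet family follows the printed schedule", {
  fam <- buildWaveletFamily(3, 50, 1.6, c(3, 10), 500)
  expect_length(fam@frequencies, 30L)
  expect_equal(fam@frequencies[1L], 3)
  expect_equal(fam@frequencies[30L], 49.4)
  expect_equal(diff(fam@frequencies), rep(1.6, 29))
  expect_equal(fam@cycles[1L], 3)
  expect_equal(fam@cycles[30L], 10)
  # affine in position along the list
  expect_equal(diff(fam@cycles), rep(7 / 29, 29), tolerance = 1e-12)
  # unit energy, odd length, envelope truncation at 1e-4
  for (k in fam@kernels) {
    expect_equal(sum(Mod(k)^2), 1, tolerance = 1e-6)
    expect_equal(length(k) %% 2L, 1L)
    expect_lt(Mod(k[1L]) / max(Mod(k)), 1.2e-4)
  }
  expect_error(buildWaveletFamily(3, 50, 1.6, c(3, 10), 80), "Nyquist|exceed")
})

test_that("a pure tone yields flat interior power at the nearest center frequency", {
  ep <- toneEpochs(10)
  fam <- buildWaveletFamily(sampleRate = 500)
  nearest <- fam@frequencies[which.min(abs(fam@frequencies - 10))]
  tfr <- tfDecompose(ep, fam, channels = "PO3", frequencies = nearest)
  pw <- tfrPower(tfr)[1, 1, 1, ]
  interior <- !tfr@edgeFlags[1, ]
  expect_lt(sd(pw[interior]) / mean(pw[interior]), 0.02)
  # zero signal: zero power
  epz <- toneEpochs(10, amp = 0)
  expect_equal(max(tfrPower(tfDecompose(epz, fam, channels = "PO3",
                                        frequencies = nearest))), 0)
  # energy scaling: amplitude a scales power by a^2
  ep3 <- toneEpochs(10, amp = 3)
  tfr3 <- tfDecompose(ep3, fam, channels = "PO3", frequencies = nearest)
  expect_equal(tfrPower(tfr3)[1, 1, 1, interior],
               9 * pw[interior], tolerance = 1e-10)
})

test_that("FFT convolution equals direct time-domain convolution", {
  fs <- 500
  set.seed(12)
  n <- 500                      # 1 s snippet
  x <- rnorm(n)
  d <- aperm(array(x, dim = c(n, 1, 10)), c(2, 3, 1))
  ep <- EpochSet(d, fs, seq(0, by = 2, length.out = n), 0,
                 data.frame(subject = 1, condition = "trained", kept = TRUE),
                 roiMontage())
  fam <- buildWaveletFamily(sampleRate = fs)
  f0 <- fam@frequencies[10L]
  tfr <- tfDecompose(ep, fam, channels = "PO3", frequencies = f0)
  k <- fam@kernels[[10L]]
  half <- (length(k) - 1L) %/% 2L
  K <- length(k)
  direct <- vapply(seq_len(n), function(i) {
    # centered linear convolution: y[i] = sum_m x[m] k[i + half - m + 1]
    m <- max(1L, i + half - K + 1L):min(n, i + half)
    sum(x[m] * k[i + half - m + 1L])
  }, complex(1))
  expect_equal(tfrPower(tfr)[1, 1, 1, ], Mod(direct)^2,
               tolerance = 1e-10)
})

test_that("percent change uses a common baseline and preserves condition ordering", {
  fam <- buildWaveletFamily(sampleRate = 250)
  cfg <- scaledSimConfig(seed = 14, nSubjects = 1, trialsPerCondition = 4)
  ep <- generateSubject(cfg, 1)
  tfr <- tfDecompose(ep, fam, channels = "PO3", frequencies = c(9.4, 11))
  pct <- percentChange(tfr, c(-400, -100))
  # P = B everywhere -> 0 %, P = 2B -> +100 %
  unif <- tfr
  unif@power[] <- 5
  expect_equal(max(abs(tfrPower(percentChange(unif, c(-400, -100))))), 0)
  dbl <- tfr
  idx <- which(tfrTime(tfr) >= -400 & tfrTime(tfr) <= -100)
  dbl@power[] <- 3
  dbl@power[, , , -idx] <- 6
  out <- percentChange(dbl, c(-400, -100))
  expect_equal(max(abs(tfrPower(out)[, , , -idx] - 100)), 0)
  # common baseline: a monotone per-(channel,freq) transform, so the
  # between-condition ordering of raw power is preserved timepoint-wise
  raw <- tfrPower(tfr)
  sgnRaw <- sign(raw[1, , , ] - raw[2, , , ])
  sgnPct <- sign(tfrPower(pct)[1, , , ] - tfrPower(pct)[2, , , ])
  expect_equal(sgnPct, sgnRaw)
  # per-condition baselining differs when conditions differ at baseline
  pc <- percentChange(tfr, c(-400, -100), scope = "per-condition",
                      conditions = trialInfo(ep)$condition)
  expect_false(isTRUE(all.equal(tfrPower(pc), tfrPower(pct))))
  expect_error(percentChange(pct, c(-400, -100)), "raw")
  expect_error(percentChange(tfr, c(-100, 300)), "precede")
})

test_that("band time course selects centers in the closed band and averages them", {
  fam <- buildWaveletFamily(sampleRate = 500)
  inBand <- fam@frequencies[fam@frequencies >= 8 & fam@frequencies <= 14]
  expect_equal(inBand, c(9.4, 11.0, 12.6))
  cfg <- scaledSimConfig(seed = 15, nSubjects = 1, trialsPerCondition = 2)
  ep <- generateSubject(cfg, 1)
  fam250 <- buildWaveletFamily(sampleRate = 250)
  tfr <- tfDecompose(ep, fam250, channels = unlist(posteriorGroups()),
                     frequencies = inBand)
  # constant tensor -> constant time course
  k <- tfr
  k@power[] <- 65
  tc <- bandTimecourse(k, c(8, 14), posteriorGroups()$leftPosterior)
  expect_equal(max(abs(tc - 65)), 0)
  # brute-force mean over the selected cells
  tc2 <- bandTimecourse(tfr, c(8, 14), posteriorGroups()$leftPosterior)
  chs <- match(posteriorGroups()$leftPosterior, tfr@channels)
  manual <- mean(tfrPower(tfr)[2, chs, , 100])
  expect_equal(tc2[2, 100], manual, tolerance = 1e-12)
  expect_error(bandTimecourse(tfr, c(60, 70), posteriorGroups()$leftPosterior),
               "band")
})

test_that("injected alpha effect is confined to the pre-target effect window", {
  cfg <- scaledSimConfig(seed = 16, nSubjects = 8, trialsPerCondition = 20,
                         alphaEffect = 0.5, alphaEffectSD = 0,
                         p1Effect = 0, p1EffectSD = 0)
  coh <- generateCohort(cfg)
  tcs <- spectralBandTimecourses(coh)
  # trained minus untrained, averaged over subjects
  diffs <- Reduce(`+`, lapply(tcs, function(x)
    x$leftPosterior$trained - x$leftPosterior$untrained)) / length(tcs)
  tm <- tcs[[1L]]$time
  inWin <- tm >= -430 & tm <= -300        # core of the injected window
  outWin <- tm >= -120 & tm <= 0          # pre-target but outside it
  expect_gt(mean(diffs[inWin]), 3 * abs(mean(diffs[outWin])))
  expect_gt(mean(diffs[inWin]), 10)
})
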