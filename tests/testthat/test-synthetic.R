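test_that("generation is deterministic and balanced", {
  cfg <- scaledSimConfig(seed = 7, nSubjects = 2, trialsPerCondition = 5)
  a <- generateSubject(cfg, 1)
  b <- generateSubject(cfg, 1)
  expect_identical(epochData(a), epochData(b))
  tb <- table(trialInfo(a)$condition)
  expect_equal(unname(tb[["trained"]]), 5L)
  expect_equal(unname(tb[["untrained"]]), 5L)
  # different subjects differ
  expect_false(identical(epochData(a), epochData(generateSubject(cfg, 2))))
  # cohort re-run is bit-for-bit identical
  c1 <- generateCohort(cfg); c2 <- generateCohort(cfg)
  expect_identical(lapply(c1$epochs, epochData), lapply(c2$epochs, epochData))
  expect_identical(c1$truth, c2$truth)
})

test_that("config validation catches bad windows, rates and correlations", {
  expect_error(scaledSimConfig(alphaEffectWindow = c(-100, -400)),
               "increasing")
  expect_error(scaledSimConfig(artifactRate = 1.5), "artifactRate")
  expect_error(scaledSimConfig(effectCorr = 2), "effectCorr")
  expect_error(scaledSimConfig(alphaFreq = 20), "8-14")
})

test_that("noise-free configuration yields the exact Gaussian P1 template", {
  cfg <- p1OnlyConfig(p1BaseAmp = 1)
  ep <- generateSubject(cfg, 1)
  time <- epochTime(ep)
  tmpl <- exp(-(time - (targetTime(ep) + 115))^2 / (2 * 15^2))
  topo <- cfg@p1Topography
  for (tr in 1:2) for (ch in c(1L, 6L))
    expect_equal(epochData(ep)[tr, ch, ], topo[ch] * tmpl, tolerance = 1e-12)
  # per-trial peak latency is exactly at the injected latency
  pk <- singleTrialPeaks(ep, "leftPosterior")
  expect_true(all(pk$detected))
  expect_true(all(abs(pk$latency_ms - 115) <= 1000 / sampleRate(ep)))
})

test_that("1/f background has log-log spectral slope near -1 (periodogram regression oracle)", {
  cfg <- scaledSimConfig(seed = 3, nSubjects = 1, trialsPerCondition = 12,
                         sampleRate = 500, noiseExponent = 1,
                         alphaBaseAmp = 0, alphaBackgroundAmp = 0,
                         p1BaseAmp = 0, p1Effect = 0, spatialMixing = 0)
  ep <- generateSubject(cfg, 1)
  d <- epochData(ep)
  fs <- sampleRate(ep)
  n <- dim(d)[3L]
  freq <- (seq_len(n) - 1) * fs / n
  sel <- freq >= 2 & freq <= 80
  slopes <- vapply(seq_len(dim(d)[1L]), function(tr) {
    pgram <- Mod(fft(d[tr, 1L, ]))^2 / n
    stats::coef(stats::lm(log(pgram[sel]) ~ log(freq[sel])))[2L]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-1)), 0.1)
})

test_that("null configuration leaves conditions statistically indistinguishable", {
  cfg <- scaledSimConfig(seed = 5, nSubjects = 12, trialsPerCondition = 12,
                         alphaEffect = 0, alphaEffectSD = 0,
                         p1Effect = 0, p1EffectSD = 0)
  coh <- generateCohort(cfg)
  # independent band-power oracle: FFT band mean over the pre-target second
  bandPower <- function(ep, cond) {
    d <- epochData(ep)
    sel <- trialInfo(ep)$condition == cond
    idx <- which(epochTime(ep) >= 0 & epochTime(ep) < targetTime(ep))
    n <- length(idx)
    freq <- (seq_len(n) - 1) * sampleRate(ep) / n
    fb <- freq >= 8 & freq <= 14
    mean(vapply(which(sel), function(tr)
      mean(Mod(fft(d[tr, 1L, idx]))[fb]^2), numeric(1)))
  }
  tr <- vapply(coh$epochs, bandPower, numeric(1), cond = "trained")
  un <- vapply(coh$epochs, bandPower, numeric(1), cond = "untrained")
  expect_lt(abs(pairedT(tr, un)$t), 3)
})

test_that("cohort effects follow the requested across-subject correlation", {
  # perfect correlation => perfect rank correlation of the recorded draws
  cfg1 <- scaledSimConfig(seed = 9, nSubjects = 12, effectCorr = 1,
                          alphaEffectSD = 0.3, p1EffectSD = 2)
  tr1 <- generateCohort(cfg1)$truth
  expect_equal(cor(tr1$true_alpha_effect, tr1$true_p1_effect,
                   method = "spearman"), 1)
  # zero correlation at n = 200: |r| within ~2/sqrt(n)
  cfg0 <- scaledSimConfig(seed = 10, nSubjects = 200, effectCorr = 0,
                          alphaEffectSD = 0.3, p1EffectSD = 2)
  eff <- t(vapply(seq_len(200), function(i)
    unlist(subjectEffects(cfg0, i)), numeric(2)))
  expect_lt(abs(cor(eff[, 1L], eff[, 2L])), 0.14)
})

test_that("artifact stream is separate from the noise stream and trips the rejector", {
  base <- scaledSimConfig(seed = 13, nSubjects = 1, trialsPerCondition = 10,
                          noiseScale = 3)
  withA <- scaledSimConfig(seed = 13, nSubjects = 1, trialsPerCondition = 10,
                           noiseScale = 3, artifactRate = 0.5)
  e0 <- generateSubject(base, 1)
  e1 <- generateSubject(withA, 1)
  flags <- trialInfo(e1)$artifact
  expect_true(any(flags) && !all(flags))
  # non-artifact epochs have the identical noise realization
  clean <- which(!flags)
  expect_identical(epochData(e1)[clean, , , drop = FALSE],
                   epochData(e0)[clean, , , drop = FALSE])
  # artifact epochs exceed the +/-75 uV screen
  rej <- rejectEpochs(e1, 75)
  expect_true(all(!rej$log$kept[flags]))
  expect_true(all(rej$log$kept[!flags]))
})
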