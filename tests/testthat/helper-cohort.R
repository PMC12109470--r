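# Scaled-down study conditions shared by the Monte-Carlo tests: short
# recordings and 4 s epochs keep replicate cohorts affordable while
# preserving the full 19-channel montage, the 95-column schema and the
# group-effect structure. The generator's *defaults* (34/30 subjects,
# 160 s, 32 s epochs) are exercised separately where counts matter.

tinyCohortSpec <- function(nMdd = 5, nHc = 5, seed = 1,
                           effect = nullEffectMap(), durationSeconds = 16)
  cohortSpec(nMdd = nMdd, nHc = nHc, durationSeconds = durationSeconds,
             effect = effect, seed = seed)

# Crop + epoch + QC + features, without the filtering/ICA stages (the
# tiny cohorts are generated artifact-free, so preprocessing is identity
# up to filtering transients).
tinyFeatures <- function(cohort, tStart = 1, tEnd = 15, window = 4,
                         overlap = 1, params = featureParams()) {
  eps <- lapply(cohort, function(r)
    qcEpochs(epochRecording(cropRecording(r, tStart, tEnd), window, overlap)))
  buildFeatureTable(eps, params = params)
}

leftTemporalAlphaEffect <- function(factor = 1.5)
  effectMap(delta = 1, theta = 1, alpha = factor, beta1 = 1, beta2 = 1,
            gamma = 1, regionScope = "Left Temporal", blinkRate = 0,
            lineNoiseAmplitude = 0)

strongGlobalEffect <- function()
  effectMap(theta = 1.5, alpha = 1.6, beta1 = 1.5, beta2 = 1.5,
            gamma = 0.8, blinkRate = 0, lineNoiseAmplitude = 0)

# A FeatureTable of pure Gaussian noise columns (no group signal).
gaussianTable <- function(n = 40, p = 10, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n * p), n, p)
    colnames(vals) <- paste0("Frontal__f", seq_len(p))
    FeatureTable(vals,
                 labels = rep(c("MDD", "HC"), length.out = n),
                 subjectIds = paste0("S", seq_len(n)))
  })
}
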