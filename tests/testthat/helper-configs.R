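# A configuration with every noise source switched off. The latent
# HER2-equivocal class is excluded: the RT-qPCR path deliberately maps
# the ERBB2 equivocal zone below the cutoff, so latent-equivocal cases
# are a genuine cross-platform ambiguity rather than noise.
zeroNoiseConfig <- function(n = 48, seed = 5, ...) {
    simConfig(n_cases = n, seed = seed,
              observer_noise_sd = c(ORI = 0, REV = 0, DIA = 0),
              her2_misgrade_prob = c(ORI = 0, REV = 0),
              replicate_sd = 0,
              her2_class_probs = c(Negative = 0.7, Equivocal = 0,
                                   Positive = 0.3),
              ...)
}
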