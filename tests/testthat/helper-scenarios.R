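# shared builders for the worked-example profiles

pe_worst_profile <- function() {
  benefit_harm_profile(b2 = 0.175, h2 = 0.05, b1 = 0.175, h1 = 0.275)
}

aml_profile <- function(h1 = 0.32) {
  benefit_harm_profile(b2 = 0.12, h2 = 0.16, b1 = 0.12, h1 = h1)
}

# neutral-system-I profile at a given benefit/harm ratio
ratio_profile <- function(ratio, h2 = 0.05, shift = 0) {
  benefit_harm_profile(b2 = ratio * h2, h2 = h2,
                       b1 = max(shift, 0), h1 = max(-shift, 0))
}
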