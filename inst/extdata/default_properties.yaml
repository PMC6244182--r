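# Default reference dielectric property table (single-pole Debye).
#
# Representative microwave-band values for breast tissues, spanning the
# range in common use for numerical breast phantoms. They are synthetic
# defaults shipped for out-of-the-box operation: substitute your own
# literature-derived table via readPropertyTable() for quantitative
# work. Units: tau in seconds, sigma_s in S/m; eps_inf and delta_eps are
# relative permittivities.
#
# fgt_lower / fgt_upper bound the fibroglandular property range; the
# linear intensity-to-property mapping interpolates between them.
# intensity ranges are in scan intensity units (matching the synthetic
# generator's default contrast).
entries:
  skin:
    eps_inf: 15.93
    delta_eps: 23.83
    tau_s: 13.0e-12
    sigma_s: 0.831
  fat:
    eps_inf: 3.14
    delta_eps: 1.71
    tau_s: 14.07e-12
    sigma_s: 0.036
  fgt_lower:
    eps_inf: 12.99
    delta_eps: 24.40
    tau_s: 13.10e-12
    sigma_s: 0.397
  fgt_upper:
    eps_inf: 22.67
    delta_eps: 30.62
    tau_s: 13.00e-12
    sigma_s: 1.033
  tumour:
    eps_inf: 20.57
    delta_eps: 33.52
    tau_s: 13.00e-12
    sigma_s: 1.202
ranges:
  skin: [80.0, 160.0]
  fat: [20.0, 100.0]
  fgt: [120.0, 260.0]
  tumour: [150.0, 300.0]
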