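# Default thresholds of the stepwise diagnostic algorithm.
# All tunables live here; the code paths contain no hidden constants.
crp_cutoff: 2.5        # mg/dL, inclusive; low-probability patients at or
                       # above it are still referred for sonography
wall_cutoff: 0.7       # mm, summed near+far temporal artery wall; inclusive
category_threshold: 2  # points; below this the clinical probability is low
age_over_70: 1         # item weights of the clinical prediction rule
headache: 1
jaw_claudication: 1
aion_unilateral: 1
aion_bilateral: 2
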