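# archfatigue pipeline configuration (defaults of the three-group experiment)
#
# Any field may be omitted; omitted fields fall back to package defaults.
# Per-group entries are passed to archfatigue::generator_params().

outdir: archfatigue_out
seed: 1
stages: [generate, segment, metrics, fit, stats]
n_per_group: 6
total_cycles: 10000
checkpoints: [1, 1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000, 9000, 10000]
orders: [1, 2, 3, 4, 5]
alpha: 0.05
ci_method: t          # t | bootstrap
wb_threshold: 50      # N, weight-bearing phase definition

groups:
  normal:
    peak_load_N: 500        # normal body weight
    b0_bai: 0.24            # first-load weight-bearing BAI (mid normal range)
    anchor_cycle: 10000
    anchor_bai: 0.218       # calibration constant: stays above low-arch 0.21
    inflection_cycle: 8000  # calibration constant (not reported for this group)
    jitter_sd_cycles: 600
    offset_sd_bai: 0.005
    d0_mm: 4.0              # first-cycle deformation -> flexibility 8 um/N
    d_retained: 1.0         # no stiffening under physiological load
    lof_r2: 0.975
  obese:
    peak_load_N: 1000       # class I-II obesity
    b0_bai: 0.24
    anchor_cycle: 1000
    anchor_bai: 0.203       # reported group mean at cycle 1000
    inflection_cycle: 6500  # reported mean inflection
    jitter_sd_cycles: 547.7 # reported across-specimen SD
    offset_sd_bai: 0.0065   # reported 95% CI half-width
    d0_mm: 6.0              # -> flexibility 6 um/N, energy 3 J at first load
    d_retained: 0.6
    lof_r2: 0.930
  insole:
    peak_load_N: 1000
    b0_bai: 0.24
    anchor_cycle: 6000
    anchor_bai: 0.200       # reported group mean at cycle 6000
    inflection_cycle: 7833  # reported mean inflection
    jitter_sd_cycles: 753   # reported across-specimen SD
    offset_sd_bai: 0.009    # reported 95% CI half-width
    d0_mm: 4.0              # -> flexibility 4 um/N, energy 2 J at first load
    d_retained: 0.75
    lof_r2: 0.936
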