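# Example probioflow run configuration: a three-condition oxygen-level
# cultivation study on synthetic data. Every field shown here has the
# same meaning as the corresponding argument of culture_scenario() /
# gate_fcm_series(); omitted fields fall back to package defaults.
seed: 1                      # master seed; mandatory

conditions:
  air_sparged:
    scenario:
      mu_max: 0.74           # 1/h, maximum specific growth rate
      dot_0: 100.0           # % air saturation at inoculation
      dot_depletion_h: 2.55  # h until dissolved oxygen reaches zero
      aerated: true          # DOT recovers after glucose depletion
      citrate_consumed: true
      yield_lactate: 0.46    # g product per g glucose
      yield_acetate: 0.11
      yield_ethanol: 0.18
    fd:
      cfu_before: 2.0e+9      # CFU/mL entering freeze-drying
      survival_pct: 61.8     # generating survivability
    acid:
      cfu_0: 1.0e+8
      death_rate: 0.08       # log10 CFU per minute at pH 2
      lod: 1000.0            # plate-count detection limit (CFU/mL)
      n_replicates: 2
    bile:
      lag_h: 5.25            # growth resumes this long after inoculation
      mu: 0.8
      od_max: 1.2
      od_0: 0.05
      n_wells: 2
    nt:
      mean_u_per_l: 370.0    # 5'-nucleotidase activity
      sd_u_per_l: 20.0
      n_biological: 2
      n_technical: 3
  n2_sparged:
    scenario:
      mu_max: 0.80
      dot_0: 5.0
      dot_depletion_h: 0.3
      aerated: false
      citrate_consumed: false
      yield_lactate: 0.42
      yield_acetate: 0.07
      yield_ethanol: 0.20
    fd: {cfu_before: 2.0e+9, survival_pct: 11.5}
    acid: {cfu_0: 1.0e+8, death_rate: 0.05, lod: 1000.0, n_replicates: 2}
    bile: {lag_h: 6.25, mu: 0.8, od_max: 1.2, od_0: 0.05, n_wells: 2}
    nt: {mean_u_per_l: 240.0, sd_u_per_l: 20.0, n_biological: 2, n_technical: 3}

gating:
  k: 4                       # viability subpopulations
  restarts: 20               # k-means initialisations per sample
  events_per_sample: 2000    # acquisition size at harvest biomass
  interval_h: 0.5            # ~two FCM samples per hour
  compare_fixed: true        # also gate with fixed wedges, report R^2

analysis:
  r2_min: 0.98               # fit floor for the mu_max window search
  bile_cutoff: 0.5           # OD marking the start of growth in bile
  biomass_gram_per_cmol: 24.6

fame:
  cv: 0.1                    # log-normal replicate noise
  n_replicates: 3
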