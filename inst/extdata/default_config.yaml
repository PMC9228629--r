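# Default configuration: chlorpyrifos / chlorpyrifos-methyl via urinary TCPy.
toxicokinetics:
  fue: 0.7
  fue_low: 0.5
  fue_high: 0.93
  urine_output_adult: 0.02        # L/kg bw/day, guidance-value convention
  urine_output_child: 0.03        # L/kg bw/day, guidance-value convention
  urine_output_food_model: 0.024  # L/kg bw/day, food-monitoring forward model
pesticides:
  - pesticide: chlorpyrifos
    molar_ratio: 0.566            # MW(TCPy)/MW(chlorpyrifos)
  - pesticide: chlorpyrifos-methyl
    molar_ratio: 0.615            # 198.43 / 322.53, standard molecular weights
pods:                             # mg/kg bw/day, chlorpyrifos
  - endpoint: overall
    value: 0.3
    basis: LOAEL                  # developmental neurotoxicity, lowest tested dose
    pesticide: chlorpyrifos
  - endpoint: long_term
    value: 0.1
    basis: NOAEL
    pesticide: chlorpyrifos
  - endpoint: short_term_ache
    value: 0.1
    basis: NOAEL
    pesticide: chlorpyrifos
  - endpoint: offspring
    value: 1
    basis: NOAEL
    pesticide: chlorpyrifos
  - endpoint: reproductive
    value: 5
    basis: NOAEL
    pesticide: chlorpyrifos
  - endpoint: carcinogenicity
    value: 10
    basis: NOAEL
    pesticide: chlorpyrifos
adi:                              # mg/kg bw/day by report year
  - pesticide: chlorpyrifos
    years: [2012, 2013, 2014, 2015]
    value: 0.01
  - pesticide: chlorpyrifos
    years: [2016, 2017, 2018, 2019]
    value: 0.001
  - pesticide: chlorpyrifos-methyl
    years: [2012, 2013, 2014, 2015, 2016, 2017, 2018, 2019]
    value: 0.01
thresholds:                       # MoE cutoffs; strict < at every boundary
  - category: loael_overall
    red_below: 300
    orange_below: 1000
    yellow_below: 10000
  - category: st_ache
    red_below: 100
    orange_below: 300
    yellow_below: 3000
  - category: noael_generic
    red_below: 100
    yellow_below: 1000
  - category: carcinogenicity
    red_below: 10000
    yellow_below: 100000
uncertainty:
  fue_low: 0.5
  fue_mode: 0.7
  fue_high: 0.93
  n_draws: 10000
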