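# Decision tree model 1: combined FET PET + MRI vs MRI alone for the
# identification of treatment-related changes in treated pediatric CNS
# lesions (83 lesions, 92 scans).
#
# Node values are the exact count ratios of the reconstructed cohort
# (display-rounding gives the published percentages 65/82/100/72/84/67).
# Deterministic-sensitivity intervals are value +/- 15 percentage points for
# the SD-8 nodes and +/- 7.5 points for the SD-4 nodes; the upper N3 end
# exceeds 100% and is treated as theoretical.
model: model1
nodes:
  N1: {value: "54/83", sd: 0.08, dsa_low: 0.5006024096, dsa_high: 0.8006024096}
  N2: {value: "68/83", sd: 0.08, dsa_low: 0.6692771084, dsa_high: 0.9692771084}
  N3: {value: "1",     sd: 0.04, dsa_low: 0.925,        dsa_high: 1.075}
  N4: {value: "21/29", sd: 0.04, dsa_low: 0.6491379310, dsa_high: 0.7991379310}
  N5: {value: "57/68", sd: 0.04, dsa_low: 0.7632352941, dsa_high: 0.9132352941}
  N6: {value: "10/15", sd: 0.04, dsa_low: 0.5916666667, dsa_high: 0.7416666667}
costs:
  pet:
    - {code: "1",      label: "Patient consultation",               amount_eur: 10.72}
    - {code: "75",     label: "Report on diagnostic findings",      amount_eur: 17.43}
    - {code: "253",    label: "Intravenous injection",              amount_eur: 9.38}
    - {code: "5430",   label: "Scintigraphy of the brain",          amount_eur: 125.91}
    - {code: "5489",   label: "FET PET with quantitative analysis", amount_eur: 786.89}
    - {code: "tracer", label: "Tracer production",                  amount_eur: 616.00}
  mri:
    - {code: "1",    label: "Patient consultation",                amount_eur: 10.72}
    - {code: "5",    label: "Physical examination",                amount_eur: 10.72}
    - {code: "75",   label: "Report on diagnostic findings",       amount_eur: 17.43}
    - {code: "346",  label: "High-pressure intravenous injection", amount_eur: 40.23}
    - {code: "3051", label: "Surcharge for perfusion imaging",     amount_eur: 75.19}
    - {code: "5700", label: "MRI with 3D and ADC reconstruction",  amount_eur: 641.16}
    - {code: "5731", label: "Additional MRI series with 3D and ADC reconstruction", amount_eur: 145.72}
    - {code: "5733", label: "Surcharge for computer analysis",     amount_eur: 46.63}
cohort:
  n_lesions: 83
  n_scans: 92
psa:
  n_draws: 10000
  cost_cv: 0.5
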