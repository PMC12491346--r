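# Decision tree model 2: FET PET alone for the identification of
# treatment-related changes in lesions already suspicious for relapse on
# routine MRI (22 lesions, one scan each).
#
# Node values are exact count ratios (published rounded values 46/90/75);
# deterministic-sensitivity intervals are value +/- 15 points (N1, SD 8) and
# +/- 7.5 points (N2/N3, SD 4).
model: model2
nodes:
  N1: {value: "10/22", sd: 0.08, dsa_low: 0.3045454545, dsa_high: 0.6045454545}
  N2: {value: "9/10",  sd: 0.04, dsa_low: 0.825,        dsa_high: 0.975}
  N3: {value: "9/12",  sd: 0.04, dsa_low: 0.675,        dsa_high: 0.825}
costs:
  pet:
    - {code: "1",      label: "Patient consultation",               amount_eur: 10.72}
    - {code: "75",     label: "Report on diagnostic findings",      amount_eur: 17.43}
    - {code: "253",    label: "Intravenous injection",              amount_eur: 9.38}
    - {code: "5430",   label: "Scintigraphy of the brain",          amount_eur: 125.91}
    - {code: "5489",   label: "FET PET with quantitative analysis", amount_eur: 786.89}
    - {code: "tracer", label: "Tracer production",                  amount_eur: 616.00}
cohort:
  n_lesions: 22
  n_scans: 22
psa:
  n_draws: 10000
  cost_cv: 0.5
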