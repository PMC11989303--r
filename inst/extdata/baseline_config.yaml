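# Baseline synthetic-cohort configuration.
#
# Calibration targets (admission level): 13,695 admissions 2013-01-01..2023-11-30,
# 57.72% female, integer age mean 59.6 / sd 14.8 / quartiles 51, 62, 70 /
# skewness -0.57 / excess kurtosis -0.04, age-category shares
# 22.7 / 21.4 / 28.8 / 27.1%, length of stay mean 4.5 / sd 5.9 days, and the
# yearly admission shares listed under year_weights (2018 peak, 2021 nadir).
# The age mixture below is a 3-component truncated Gaussian fitted offline to
# those moments/quantiles; the month multipliers encode the winter excess, the
# October spike in females and the flat autumn in males; length of stay is
# lognormal with matched mean/sd.
n_admissions: 13695
p_female: 0.5772
seed: 20130101
repeat_admission_rate: 0.2
age_mixture:
  - {weight: 0.217223, mean: 38.5591, sd: 15.7069}
  - {weight: 0.485705, mean: 60.6986, sd: 10.5113}
  - {weight: 0.297072, mean: 71.4381, sd: 8.1485}
year_weights:
  "2013": 0.105105105105
  "2014": 0.100100100100
  "2015": 0.088088088088
  "2016": 0.074074074074
  "2017": 0.097097097097
  "2018": 0.128128128128
  "2019": 0.120120120120
  "2020": 0.065065065065
  "2021": 0.050050050050
  "2022": 0.078078078078
  "2023": 0.094094094095
month_weights_by_sex:
  F: [1.15, 1.18, 1.20, 1.05, 0.95, 0.85, 0.78, 0.72, 0.95, 1.25, 1.05, 0.87]
  M: [1.35, 1.25, 1.15, 1.05, 0.97, 0.87, 0.80, 0.75, 0.97, 0.97, 0.97, 0.90]
los_lognormal:
  mu: 1.0039430437
  sigma: 1.0001343441
background_codes:
  - {code: I10, p: 0.10}
  - {code: J96.0, p: 0.05}
  - {code: J96.1, p: 0.015}
  - {code: E78.5, p: 0.03}
  - {code: K21.9, p: 0.02}
blocks_by_age_group:
  "18-49":
    - label: lifestyle and airway
      codes: [Z72.0, J43.9, B37.0, B37.1, E66.0, E11.9, J30.4, J18.9, J84.1]
      p_active: 0.40
      p_code_given_active: 0.30
      p_code_background: 0.01
    - label: infection and frailty
      codes: [N39.0, A41.9, E87.6, D53.9, D64.8, J15.9, U07.1]
      p_active: 0.30
      p_code_given_active: 0.30
      p_code_background: 0.01
    - label: morbid obesity
      codes: [E66.9, K76.0]
      p_active: 0.15
      p_code_given_active: 0.50
      p_code_background: 0.01
  "50-59":
    - label: metabolic and infection
      codes: [E66.0, R73, B37.0, N39.0, Z72.0, J18.9, F41.2, D53.9, U07.1]
      p_active: 0.40
      p_code_given_active: 0.30
      p_code_background: 0.01
    - label: chronic pulmonary and cardiovascular
      codes: [J44.0, J44.9, Z99.1, I25.9, I50.0, I11.0, I48, E78.2, F17.2, J92.9]
      p_active: 0.35
      p_code_given_active: 0.30
      p_code_background: 0.01
    - label: neurological
      codes: [G20, I63.8, I24.9]
      p_active: 0.10
      p_code_given_active: 0.40
      p_code_background: 0.005
  "60-69":
    - label: moderate cardiovascular and sepsis
      codes: [I34.0, I50.9, E87.1, A41.9, I46.9, K76.0, R74.0, F41.9, K21.0, U07.1]
      p_active: 0.40
      p_code_given_active: 0.30
      p_code_background: 0.01
    - label: advanced cardiovascular and obesity
      codes: [I25.9, I27.9, I48, I50.0, I11.0, E11.9, E66.0, B37.0, N39.0, J44.0,
              Z99.1, J84.1, D53.9, C34.9]
      p_active: 0.40
      p_code_given_active: 0.25
      p_code_background: 0.01
    - label: cataracts
      codes: [H26.9]
      p_active: 0.10
      p_code_given_active: 0.60
      p_code_background: 0.005
  "70+":
    - label: advanced cardiovascular sepsis and neurological
      codes: [I34.0, I50.9, I70.0, E87.6, A41.9, I46.9, G20, I63.9, F03, U07.1,
              I69.3, R42]
      p_active: 0.45
      p_code_given_active: 0.30
      p_code_background: 0.01
    - label: comorbidity burden
      codes: [I50.0, I25.9, I48, I11.0, B37.0, J44.0, Z99.1, J84.1, J15.9, E11.9,
              N39.0, D53.9, C34.9, F41.2, J92.9, N40, I26.9, E87.0]
      p_active: 0.45
      p_code_given_active: 0.25
      p_code_background: 0.01
    - label: pulmonary metastasis
      codes: [C78.0]
      p_active: 0.08
      p_code_given_active: 0.60
      p_code_background: 0.005
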