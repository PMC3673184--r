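# Default coefficient catalogue for the cadmium toxicokinetic model.
#
# Units: transfer coefficients are first-order fractions moved per day;
# absorption and mucociliary fractions are unitless; creatinine excretion is
# g/day; ages are years.  The schema is strict: every key below is required
# and unknown keys are rejected.
#
# Compartments: B1 fast blood, B2 slowly exchanging blood (red cells),
# B3 plasma metallothionein pool, L liver, K kidney, T other tissue.
absorption:
  gut_male: 0.05          # fraction of ingested Cd absorbed to fast blood
  gut_female: 0.10        # higher: low iron stores promote uptake in women
  lung: 0.14              # fraction of inhaled Cd absorbed to blood
  mucociliary_to_gut: 0.05  # inhaled fraction cleared to the gut
transfer:
  k_B1B2: 0.04
  k_B2B1: 0.02
  k_B1B3: 0.10
  k_B1L: 0.25
  k_B1K: 0.01
  k_B1T: 0.10
  k_TB1: 1.8992e-04       # other-tissue return, half-life ~10 y
  k_B1F: 0.10             # biliary / gastrointestinal loss from fast blood
  k_B3K: 0.10             # plasma metallothionein filtered into kidney
  k_B3U: 0.005            # direct urinary loss from plasma pool
  k_LB3: 3.1653e-04       # liver release to plasma, half-life ~6 y
  k_LF: 2.0e-05           # biliary loss from liver
  k_KU: 9.9946e-05        # kidney elimination to urine, half-life ~19 y
  k_KB1: 0.0              # kidney return to blood (off by default)
creatinine:               # daily urinary creatinine excretion, g/day
  male:
    age: [0, 3, 20, 50, 80, 100]
    value: [0.05, 0.2, 1.5, 1.5, 1.0, 1.0]
  female:
    age: [0, 3, 20, 50, 80, 100]
    value: [0.05, 0.2, 1.0, 1.0, 0.7, 0.7]
diet_age_scaling:         # multiplier on adult dietary intake by age
  age: [0, 18, 100]
  value: [0.3, 1.0, 1.0]
smoking:
  start_age: 18           # years; default smoking initiation age
  cd_per_pack:            # inhaled Cd dose per pack of 20 cigarettes, ug
    Bangkok: 5.5
    MaeSot: 6.5
timestep: 1               # days; explicit-step integration
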