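chem:
  name: benzo(a)pyrene
  molar_mass: 252.300000000000011
  vapor_pressure: 7.0e-07
  solubility: 1.52e-05
  log_kow: 6.04
  henry: 0.046052631578947
  koc: 449556.060418705805205
  melting_point: 452.0
  half_life:
    air: 200.0
    water: 70.0
    soil: 3650.0
    sediment: 2300.0
env:
  compartments:
    air:
      volume: 6582000000000.0
      area: 6582000000.0
      frac_aerosol: 3.0e-10
    water:
      volume: 2172060000.0
      area: 724020000.0
      frac_solids: 2.5e-05
      frac_biota: 1.0e-07
      foc_solids: 0.2
      solids_density: 2400.0
    soil:
      volume: 29289900.0
      area: 5857980000.0
      frac_solids: 0.5
      frac_air: 0.2
      frac_water: 0.3
      foc: 0.02
      solids_density: 2400.0
      builtup_fraction: 0.15
    sediment:
      volume: 21720600.0
      area: 724020000.0
      frac_solids: 0.2
      frac_water: 0.8
      foc: 0.05
      solids_density: 2400.0
  transport:
    kaw_air: 72.0
    kaw_water: 0.72
    dry_dep: 10.0
    scavenging: 2000.0
    kas_air: 24.0
    ksa_soil_air: 0.5
    ksa_soil_water: 0.00024
    sed_dep: 2.4e-07
    sed_resus: 1.2e-07
    ksw_diff: 0.0024
    runoff_water: 0.00039
    runoff_solids: 2.3e-08
    G_irr: 14000000.0
    air_cross_section: 12000.0
    G_water: 260000000.0
  ref_temperature: 288.550000000000011
config:
  years:
  - 2002
  - 2003
  - 2004
  - 2005
  - 2006
  - 2007
  - 2008
  emissions:
    year:
    - 2002
    - 2003
    - 2004
    - 2005
    - 2006
    - 2007
    - 2008
    air_transport:
    - 0.43
    - 0.5
    - 0.51
    - 0.59
    - 0.62
    - 0.64
    - 0.69
    air_industry:
    - 0.89
    - 1.04
    - 1.06
    - 1.22
    - 1.28
    - 1.32
    - 1.43
    air_total:
    - 1.32
    - 1.54
    - 1.58
    - 1.82
    - 1.9
    - 1.96
    - 2.12
    water_industry:
    - 0.17
    - 0.16
    - 0.15
    - 0.15
    - 0.14
    - 0.13
    - 0.12
  mean_temperature: 288.550000000000011
  seasonal_amplitude: 12.5
  temperature_sd: 2.0
  rain_probability: 0.333333333333333
  annual_rain_mm: 1000.0
  wind_meanlog: 1.01861228866811
  wind_sdlog: 0.4
  direction_weights:
    'N': 0.5
    NE: 1.5
    E: 3.0
    SE: 2.0
    S: 0.5
    SW: 0.5
    W: 1.0
    NW: 0.5
  f0:
    air: 9.999999999999999e-12
    water: 1.0e-10
    soil: 9.999999999999999e-12
    sediment: 1.0e-10
  c_a: 9.999999999999999e-12
  c_w: 1.0e-07
exposure:
  food:
    item:
    - cereals
    - vegetables
    - meat
    - eggs
    - milk
    m:
    - 400.0
    - 300.0
    - 80.0
    - 30.0
    - 50.0
    v:
    - 0.015
    - 0.003
    - 0.28
    - 0.1
    - 0.035
  m_fish: 30.0
  v_fish: 0.05
  rho_lipid: 915000.0
  body_weight: 60.0
  skin_area: 1.6
  k_p: 0.03
  shower_time: 0.007
  food_origin_fraction: 1.0
drs:
  SF_f: 0.00094
  SF_d: 0.0044
  UR_w: 2.8e-08
  UR_i: 5.4e-08
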