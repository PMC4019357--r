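# Default allometric equation registry.
#
# LN_LN block: the generalized national ln-ln aboveground-biomass equations
# for 10 species groups, biomass_kg = exp(b0 + b1 * ln(dbh_cm)); r_squared and
# n_obs are the fit statistics of the source regressions and drive the
# allometric-error simulation; dbh_range is the validity range in cm.
#
# VOLUME_CRM and SPECIES_SPECIFIC blocks: SYNTHETIC plausible defaults (no
# regional coefficient table is redistributable here). CRM chain:
# bole_volume_m3 = a + b * dbh_cm^2 * bole_height_m; bole_kg = volume *
# wood_density (kg/m3); total_kg = bole_kg / bole_ratio.
equations:
  - {family: LN_LN, group: aspen_alder_cottonwood_willow,
     coefficients: {b0: -2.2094, b1: 2.3867},
     r_squared: 0.953, n_obs: 230, dbh_range: [2.2, 70.0],
     source: national ln-ln group equations}
  - {family: LN_LN, group: soft_maple_birch,
     coefficients: {b0: -1.9123, b1: 2.3651},
     r_squared: 0.958, n_obs: 316, dbh_range: [2.5, 66.0],
     source: national ln-ln group equations}
  - {family: LN_LN, group: mixed_hardwood,
     coefficients: {b0: -2.4800, b1: 2.4835},
     r_squared: 0.980, n_obs: 289, dbh_range: [2.5, 56.0],
     source: national ln-ln group equations}
  - {family: LN_LN, group: hard_maple_oak_hickory_beech,
     coefficients: {b0: -2.0127, b1: 2.4342},
     r_squared: 0.988, n_obs: 485, dbh_range: [2.5, 73.0],
     source: national ln-ln group equations}
  - {family: LN_LN, group: cedar_larch,
     coefficients: {b0: -2.0336, b1: 2.2592},
     r_squared: 0.981, n_obs: 196, dbh_range: [2.5, 250.0],
     source: national ln-ln group equations}
  - {family: LN_LN, group: douglas_fir,
     coefficients: {b0: -2.2304, b1: 2.4435},
     r_squared: 0.992, n_obs: 165, dbh_range: [2.5, 210.0],
     source: national ln-ln group equations}
  - {family: LN_LN, group: true_fir_hemlock,
     coefficients: {b0: -2.5384, b1: 2.4814},
     r_squared: 0.992, n_obs: 395, dbh_range: [2.5, 230.0],
     source: national ln-ln group equations}
  - {family: LN_LN, group: pine,
     coefficients: {b0: -2.5356, b1: 2.4349},
     r_squared: 0.987, n_obs: 331, dbh_range: [2.5, 180.0],
     source: national ln-ln group equations}
  - {family: LN_LN, group: spruce,
     coefficients: {b0: -2.0773, b1: 2.3323},
     r_squared: 0.988, n_obs: 212, dbh_range: [2.5, 250.0],
     source: national ln-ln group equations}
  - {family: LN_LN, group: juniper_oak_mesquite,
     coefficients: {b0: -0.7152, b1: 1.7029},
     r_squared: 0.938, n_obs: 61, dbh_range: [2.5, 78.0],
     source: national ln-ln group equations}

  - {family: VOLUME_CRM, group: mixed_hardwood,
     coefficients: {a: 0.0018, b: 3.70e-05, wood_density: 520.0, bole_ratio: 0.78},
     r_squared: 0.96, n_obs: 240, dbh_range: [12.7, 80.0],
     source: synthetic regional defaults}
  - {family: VOLUME_CRM, group: soft_maple_birch,
     coefficients: {a: 0.0016, b: 3.55e-05, wood_density: 490.0, bole_ratio: 0.77},
     r_squared: 0.95, n_obs: 210, dbh_range: [12.7, 70.0],
     source: synthetic regional defaults}
  - {family: VOLUME_CRM, group: hard_maple_oak_hickory_beech,
     coefficients: {a: 0.0021, b: 3.85e-05, wood_density: 600.0, bole_ratio: 0.80},
     r_squared: 0.97, n_obs: 320, dbh_range: [12.7, 85.0],
     source: synthetic regional defaults}
  - {family: VOLUME_CRM, group: pine,
     coefficients: {a: 0.0014, b: 3.30e-05, wood_density: 460.0, bole_ratio: 0.72},
     r_squared: 0.96, n_obs: 260, dbh_range: [12.7, 90.0],
     source: synthetic regional defaults}
  - {family: VOLUME_CRM, group: aspen_alder_cottonwood_willow,
     coefficients: {a: 0.0015, b: 3.40e-05, wood_density: 380.0, bole_ratio: 0.74},
     r_squared: 0.94, n_obs: 150, dbh_range: [12.7, 65.0],
     source: synthetic regional defaults}

  - {family: SPECIES_SPECIFIC, species: red_maple, group: soft_maple_birch,
     coefficients: {b0: -1.8560, b1: 2.3700},
     r_squared: 0.97, n_obs: 150, dbh_range: [2.5, 60.0],
     source: synthetic local defaults}
  - {family: SPECIES_SPECIFIC, species: white_oak, group: hard_maple_oak_hickory_beech,
     coefficients: {b0: -1.9000, b1: 2.4400},
     r_squared: 0.98, n_obs: 180, dbh_range: [2.5, 70.0],
     source: synthetic local defaults}
  - {family: SPECIES_SPECIFIC, species: tulip_poplar, group: mixed_hardwood,
     coefficients: {b0: -2.3600, b1: 2.4900},
     r_squared: 0.97, n_obs: 120, dbh_range: [2.5, 60.0],
     source: synthetic local defaults}
  - {family: SPECIES_SPECIFIC, species: loblolly_pine, group: pine,
     coefficients: {b0: -2.4100, b1: 2.4400},
     r_squared: 0.98, n_obs: 140, dbh_range: [2.5, 70.0],
     source: synthetic local defaults}
  - {family: SPECIES_SPECIFIC, species: sweetgum, group: mixed_hardwood,
     coefficients: {b0: -2.4200, b1: 2.5000},
     r_squared: 0.97, n_obs: 110, dbh_range: [2.5, 60.0],
     source: synthetic local defaults}
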