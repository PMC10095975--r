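scenarios:
  whole_cell_22C:
    temperature_label: 22C
    compartment_label: whole_cell
    invertase:
      v_max: 5.0
      k_m: 5.0
      k_i_glc: 4.0
      k_i_frc: 8.0
    fluxes:
      r_in: 0.80000000000000004
      efflux_kind: michaelis_menten
      efflux_glc:
        v_max: 2.0
        k_m: 5.0
      efflux_frc:
        v_max: 2.0
        k_m: 5.0
    grid:
      glc_range:
      - 1.0
      - 3.0
      frc_range:
      - 1.0
      - 3.0
      suc_planes:
      - 1.0
      - 2.0
      - 3.0
      n_glc: 50
      n_frc: 50
      units: umol_gFW
  whole_cell_4C:
    temperature_label: 4C
    compartment_label: whole_cell
    invertase:
      v_max: 1.5
      k_m: 5.0
      k_i_glc: 4.0
      k_i_frc: 8.0
    fluxes:
      r_in: 0.23999999999999999
      efflux_kind: michaelis_menten
      efflux_glc:
        v_max: 2.0
        k_m: 5.0
      efflux_frc:
        v_max: 2.0
        k_m: 5.0
    grid:
      glc_range:
      - 5.0
      - 15.0
      frc_range:
      - 5.0
      - 15.0
      suc_planes:
      - 4.0
      - 6.0
      - 8.0
      n_glc: 50
      n_frc: 50
      units: umol_gFW
compartments:
  cytosol:
    volume_fraction: 0.05
    sugar_fractions:
      sucrose:
        22C: 0.5
        4C: 0.40000000000000002
      hexose:
        22C: 0.29999999999999999
        4C: 0.29999999999999999
  vacuole:
    volume_fraction: 0.80000000000000004
    sugar_fractions:
      sucrose:
        22C: 0.25
        4C: 0.33000000000000002
      hexose:
        22C: 0.55000000000000004
        4C: 0.5
isoforms:
  cytosol:
    22C:
      v_max: 5.0
      k_m: 8.0
      k_i_glc: 4.0
      k_i_frc: 8.0
      r_in: 0.80000000000000004
    4C:
      v_max: 1.5
      k_m: 8.0
      k_i_glc: 4.0
      k_i_frc: 8.0
      r_in: 0.23999999999999999
  vacuole:
    22C:
      v_max: 8.0
      k_m: 2.0
      k_i_glc: 4.0
      k_i_frc: 8.0
      r_in: 0.20000000000000001
    4C:
      v_max: 2.39999999999999991
      k_m: 2.0
      k_i_glc: 4.0
      k_i_frc: 8.0
      r_in: 0.06
subcellular_sucrose_planes:
  cytosol:
    22C:
    - 8.0
    - 16.0
    - 24.0
    4C:
    - 25.60000000000000142
    - 38.39999999999999858
    - 51.20000000000000284
  vacuole:
    22C:
    - 0.25
    - 0.5
    - 0.75
    4C:
    - 1.32000000000000006
    - 1.97999999999999998
    - 2.64000000000000012
whole_cell_hexose_amounts:
  22C:
  - 1.0
  - 3.0
  4C:
  - 5.0
  - 15.0
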