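# Systems PK-PD parameters for trastuzumab-vc-MMAE in HER2-high (N87) and
# HER2-low (GFP-MCF7) xenografts.  Values, units, precision (CV%) and
# fixed/estimated provenance follow the published parameterization; entries
# under `assumptions` are model-housekeeping constants the source left
# implicit, surfaced here so they can be overridden from configuration.
name: tvcmmae
plasma:
  CL_ADC:   {value: 0.033,  unit: L/day/kg,  cv_pct: 4.8,  role: estimated}
  CLD_ADC:  {value: 0.0585, unit: L/day/kg,  cv_pct: 12.6, role: estimated}
  V1_ADC:   {value: 0.084,  unit: L/kg,      cv_pct: 7.3,  role: estimated}
  V2_ADC:   {value: 0.051,  unit: L/kg,      cv_pct: 5.2,  role: estimated}
  CL_Drug:  {value: 18.40,  unit: L/day/kg,  role: fixed}
  CLD_Drug: {value: 1.84,   unit: L/day/kg,  role: fixed}
  V1_Drug:  {value: 0.136,  unit: L/kg,      role: fixed}
  V2_Drug:  {value: 0.523,  unit: L/kg,      role: fixed}
  Kdec_P:   {value: 0.323,  unit: 1/day,     cv_pct: 8.8,  role: estimated}
  DAR0:     {value: 4.0,    unit: mol/mol,   role: fixed}
tumor_distribution:
  R_cap:    {value: 8.0,    unit: um,        role: fixed}
  R_Krogh:  {value: 75.0,   unit: um,        role: fixed}
  P_ADC:    {value: 334.0,  unit: um/day,    role: fixed}
  P_Drug:   {value: 21000.0, unit: um/day,   role: fixed}
  D_ADC:    {value: 0.022,  unit: cm2/day,   role: fixed}
  D_Drug:   {value: 0.25,   unit: cm2/day,   role: fixed}
  eps_ADC:  {value: 0.24,   unit: unitless,  role: fixed}
  eps_Drug: {value: 0.44,   unit: unitless,  role: fixed}
single_cell:
  Kon_ADC:  {value: 0.03,   unit: 1/nM/h,    role: fixed}
  Koff_ADC: {value: 0.014,  unit: 1/h,       role: fixed}
  Kint_ADC: {value: 0.11,   unit: 1/h,       role: fixed}
  Kdeg_ADC: {value: 0.353,  unit: 1/h,       role: fixed}
  Kon_Tub:  {value: 0.0183, unit: 1/nM/h,    role: fixed}
  Koff_Tub: {value: 0.545,  unit: 1/h,       role: fixed}
  Tub_total: {value: 65.0,  unit: nM,        role: fixed}
  Kin_Drug: {value: 8.33,   unit: 1/h,       role: fixed}
  Kout_Drug: {value: 0.046, unit: 1/h,       role: fixed}
  Ag_ex:
    n87:  {value: 185000.0, unit: receptors/cell, cv_pct: 2.8, role: estimated}
    mcf7: {value: 22400.0,  unit: receptors/cell, cv_pct: 3.2, role: estimated}
pd:
  Kmax:     {value: 1.03,   unit: 1/day,     cv_pct: 31.3, role: estimated}
  KC50:     {value: 96.8,   unit: percent,   cv_pct: 13.2, role: estimated}
  gamma:    {value: 15.02,  unit: unitless,  cv_pct: 38.6, role: estimated}
  tau:      {value: 2.03,   unit: day,       role: estimated}
  iiv_Kmax: {value: 10.16,  unit: percent,   cv_pct: 47.0, role: estimated}
  iiv_tau:  {value: 19.4,   unit: percent,   cv_pct: 32.0, role: estimated}
  DT:
    n87:  {value: 13.5,     unit: day, cv_pct: 11.4, role: estimated}
    mcf7: {value: 10.6,     unit: day, cv_pct: 18.7, role: estimated}
assumptions:
  MW_ADC:        {value: 150000.0, unit: g/mol, note: "IgG1 (~148 kDa) plus ~4 vc-MMAE linkers"}
  body_weight:   {value: 0.02,    unit: kg,     note: "typical SCID mouse"}
  V_cell:        {value: 1.0e-12, unit: L/cell, note: "1 pL, typical carcinoma cell"}
  cells_per_mm3: {value: 1.0e+5,  unit: cells/mm3, note: "1e8 cells/g at density 1 g/mL"}
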