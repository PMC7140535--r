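# De-novo pyrimidine biosynthesis reaction network used by the teriflunomide
# sub-model: 29 species, 13 enzymatic reactions.  The topology follows the
# canonical de-novo pyrimidine pathway (glutamine/aspartate -> carbamoyl
# phosphate -> dihydroorotate -> orotate -> UMP -> UTP/CTP -> nucleic-acid
# demand); exact species composition and kinetic constants are a synthetic
# reconstruction, not literature measurements.  The DHODH step carries the
# non-competitive teriflunomide inhibition
# v = Vmax*S/((Km+S)*(1+I/Ki)).
#
# Per-species fields: init (concentration, au), nitrogen (atoms, used by the
# closed-system conservation check), boundary (clamped concentration).
species:
  Gln_ext:        {init: 10,  nitrogen: 2, boundary: true}
  Asp_ext:        {init: 10,  nitrogen: 1, boundary: true}
  Gln:            {init: 1,   nitrogen: 2, boundary: false}
  Asp:            {init: 1,   nitrogen: 1, boundary: false}
  R5P:            {init: 5,   nitrogen: 0, boundary: true}
  ATP:            {init: 10,  nitrogen: 5, boundary: true}
  AMP:            {init: 1,   nitrogen: 5, boundary: true}
  ADP:            {init: 1,   nitrogen: 5, boundary: true}
  Pi:             {init: 1,   nitrogen: 0, boundary: true}
  HCO3:           {init: 5,   nitrogen: 0, boundary: true}
  H2O:            {init: 1,   nitrogen: 0, boundary: true}
  CarbP:          {init: 0,   nitrogen: 1, boundary: false}
  Glu:            {init: 1,   nitrogen: 1, boundary: true}
  CarbamoylAsp:   {init: 0,   nitrogen: 2, boundary: false}
  DHO:            {init: 0,   nitrogen: 2, boundary: false}
  CoQ:            {init: 2,   nitrogen: 0, boundary: false}
  CoQH2:          {init: 0,   nitrogen: 0, boundary: false}
  O2:             {init: 5,   nitrogen: 0, boundary: true}
  Orotate:        {init: 0,   nitrogen: 2, boundary: false}
  PRPP:           {init: 1,   nitrogen: 0, boundary: false}
  PPi:            {init: 1,   nitrogen: 0, boundary: true}
  OMP:            {init: 0,   nitrogen: 2, boundary: false}
  CO2:            {init: 1,   nitrogen: 0, boundary: true}
  UMP:            {init: 0,   nitrogen: 2, boundary: false}
  UDP:            {init: 0,   nitrogen: 2, boundary: false}
  UTP:            {init: 0,   nitrogen: 2, boundary: false}
  CTP:            {init: 0,   nitrogen: 3, boundary: false}
  RNA:            {init: 0,   nitrogen: 5, boundary: true}
  Teriflunomide:  {init: 0,   nitrogen: 2, boundary: true}
reactions:
  - name: aa_uptake
    law: mass_action
    k: 0.5
    substrates: {Gln_ext: 1, Asp_ext: 1}
    products: {Gln: 1, Asp: 1}
  - name: prpp_synthetase
    law: mass_action
    k: 0.2
    substrates: {R5P: 1, ATP: 1}
    products: {PRPP: 1, AMP: 1}
  - name: cps2
    law: michaelis_menten
    vmax: 4
    km: 0.5
    mm_substrate: Gln
    substrates: {Gln: 1, HCO3: 1, ATP: 2, H2O: 1}
    products: {CarbP: 1, Glu: 1, ADP: 2, Pi: 1}
  - name: atcase
    law: mass_action
    k: 2
    substrates: {CarbP: 1, Asp: 1}
    products: {CarbamoylAsp: 1, Pi: 1}
  - name: dhoase
    law: mass_action
    k: 2
    substrates: {CarbamoylAsp: 1}
    products: {DHO: 1, H2O: 1}
  - name: dhodh
    law: michaelis_menten
    vmax: 2
    km: 0.5
    mm_substrate: DHO
    inhibitor: Teriflunomide
    ki: 1.4
    substrates: {DHO: 1, CoQ: 1}
    products: {Orotate: 1, CoQH2: 1}
  - name: coq_reoxidation
    law: mass_action
    k: 5
    substrates: {CoQH2: 1, O2: 1}
    products: {CoQ: 1, H2O: 1}
  - name: oprt
    law: mass_action
    k: 2
    substrates: {Orotate: 1, PRPP: 1}
    products: {OMP: 1, PPi: 1}
  - name: omp_decarboxylase
    law: mass_action
    k: 4
    substrates: {OMP: 1}
    products: {UMP: 1, CO2: 1}
  - name: ump_kinase
    law: mass_action
    k: 1
    substrates: {UMP: 1, ATP: 1}
    products: {UDP: 1, ADP: 1}
  - name: ndp_kinase
    law: mass_action
    k: 1
    substrates: {UDP: 1, ATP: 1}
    products: {UTP: 1, ADP: 1}
  - name: ctp_synthase
    law: michaelis_menten
    vmax: 1
    km: 1
    mm_substrate: UTP
    substrates: {UTP: 1, Gln: 1, ATP: 1}
    products: {CTP: 1, Glu: 1, ADP: 1, Pi: 1}
  - name: nucleic_acid_demand
    law: mass_action
    k: 0.5
    substrates: {UTP: 1, CTP: 1}
    products: {RNA: 1, PPi: 2}
readout_reaction: nucleic_acid_demand
inhibited_reaction: dhodh
dose_to_concentration: 0.1
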