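# Calibration constants for the MS simulator.  Every tunable that is not a
# literature value from the entity table or a drug label lives here; rule
# probabilities are per 8-hour step unless noted.

# interaction probabilities
priming_scale: 4.0       # global gain on specific T-cell priming
p_ig_ag: 0.05            # immunocomplex formation per IgG-antigen pairing
p_capture_apc: 0.02      # aspecific antigen capture per unit scanned (M, DC)
p_opsonize: 0.002        # IgG opsonization per IgG-ODC pairing
p_kill_m: 0.1            # macrophage kill of an opsonized ODC per scan
p_div: 0.35             # clonal division per step (IL-2 present)
p_mem: 0.005             # active T -> resting memory per step
p_anergy: 0.05           # anergy after unproductive no-B7 engagement
p_adcc: 0.3              # death of antibody-bound cells per step
p_anti_cd20: 0.1         # B-cell binding per step while anti-CD20 active
hayflick_limit: 8        # max divisions per lineage
p_hypermutation: 0.3     # one-bit receptor flip at B differentiation
tc_scan_cap: 30          # targets a cytotoxic T cell scans per step

# trafficking
p_apc_migrate: 0.2       # presenting APC, white matter -> lymph node
p_ingress: 0.25          # activated effector T, lymph node -> white matter
igg_wm_fraction: 0.1     # IgG circulating into white matter per step
mbp_drain_fraction: 0.02 # free myelin antigen draining to the lymph node

# secretion (units per step per cell)
secrete_units: 2
il12_units: 1
igg_per_plasma_step: 2
mbp_per_death: 8         # MBP units released per dying oligodendrocyte
chem_per_kill: 20        # chemokine units released per immune-mediated kill

# regulatory compartment
treg_count: 44           # resting regulatory T cells per uL (model addition)
treg_tonic: 0.03         # tonic activation per step, healthy regulation
treg_pres_bonus: 0.2     # extra activation under local inflammation
treg_floor: 0.05         # lower bound of the impairment damping factor
treg_impair_weight: 1.2  # how strongly impairment damps Treg activation
treg_active_half_life: 7   # days of sustained suppressive activity
k_suppression: 2         # mean IL-10+TGFB per site halving effector shutdown
suppression_exponent: 3  # sharper suppression of priming than of shutdown
il2_treg_threshold: 8    # mean IL-2 per site recruiting regulatory T cells
deact_max: 0.4           # max per-step shutdown of active effectors

# homeostasis and tissue
homeostasis_cv: 0.01     # stationary coefficient of variation of OU pools
wm_apc_fraction: 0.3     # resident white-matter APCs as fraction of the pool

# risk factors
d_mimic: 1               # Hamming distance EBV epitope <-> MBP peptide
hla_capture_boost: 1.5   # autoantigen capture multiplier under HLA risk
ebv_units: 1000          # antigen units per EBV reactivation episode
ebv_reactivation_days: 180
vitamin_d_factor: {normal: 1.0, low: 0.75, very_low: 0.45}
smoking_factor: {negligible: 1.0, not_negligible: 0.7}

# patient-feature mapping
apoptosis_p_min: 2.0e-05
apoptosis_p_max: 1.0e-03
lesion_ref: 80
impairment_base: 0.3
ocb_impairment_bonus: 0.3
age_ref: 30
reactivity_min: 0.5
reactivity_max: 2.0
pregnancy_factor: 0.5

# reference relapsing-remitting scenario (impaired regulation)
ms_reference_impairment: 0.6
ms_reference_apoptosis: 5.0e-04

# drug effect magnitudes
ifnb1a_th1_to_th2: 0.4
ifnb1a_mhc2_scale: 0.6
ifnb1a_treg_boost: 1.5
fingolimod_egress: 0.05
natalizumab_ingress: 0.1
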