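# National-pilot scenario: the published setting mix and national
# prevalences as generator inputs. Synthetic — no real patient data.
n_orgs: 10
wards_per_org: 5
patients_per_ward_month: 25
months: 6
seed: 2012
start_month: "2012-07"
setting_mix:
  hospital_ward: 0.90
  own_home: 0.03
  nursing_home: 0.02
  other: 0.05
p_pu_old: 0.065
p_pu_new: 0.0102
pu_category_mix:
  "2": 0.60
  "3": 0.30
  "4": 0.10
p_fall: 0.0322
p_fall_harm_given_fall: 0.3913043478260870
fall_harm_severity_mix:
  low: 0.75
  moderate: 0.18
  severe: 0.05
  death: 0.02
p_cath: 0.1673
p_uti_given_cath: 0.1213388690974298
p_uti_new_given_uti: 0.5123152709359606
p_uti_no_cath: 0.03
p_vte_na: 0.05
p_vte_assessed: 0.6927
p_at_risk: 0.55
p_prophylaxis_given_risk: 0.5516
p_vte_treated: 0.0364
p_vte_new_given_treated: 0.4148351648351648
vte_type_mix:
  dvt: 0.55
  pe: 0.35
  other: 0.10
frailty_sd: 0
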