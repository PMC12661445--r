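total_calcium_uM: 500.0
species:
- name: DMNP.caged
  total_uM: 500.0
  kd_uM: 0.005
  D_um2_per_s: 600.0
  mobile: yes
- name: DMNP.photolyzed
  total_uM: 0.0
  kd_uM: 3000.0
  D_um2_per_s: 600.0
  mobile: yes
- name: EGTA
  total_uM: 100.0
  kd_uM: 0.15
  D_um2_per_s: 400.0
  mobile: yes
- name: Rhod5N
  total_uM: 25.0
  kd_uM: 230.0
  D_um2_per_s: 400.0
  mobile: yes
- name: Tcb2
  total_uM: 250.0
  kd_uM: 200.0
  D_um2_per_s: 400.0
  mobile: yes

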