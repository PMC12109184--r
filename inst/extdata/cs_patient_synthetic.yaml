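# SYNTHETIC cardiogenic-shock fixture: the deterministic tuner's output for
# the packaged healthy reference (see tools/make_fixtures.R). It stands in
# for an unpublished reference parameterisation; only the four shock bounds
# (SBP < 90, SVRi < 1800, PCWP > 15, CI < 2.2) are authoritative.
heart_rate: 90.0
bsa: 1.8
blood_volume: 5506.0546875
timing:
  ts_v_coef: 0.35
  ts_a_coef: 0.17
  av_delay: 0.16
  av_delay_ref_period: 0.857
  peak_frac: 0.5
chambers:
  lv:
    Ees: 0.763832092285
    V0: 15
    A: 0.35
    B: 0.0432
    V_init: 120
  rv:
    Ees: 0.304012636524
    V0: 15
    A: 0.22
    B: 0.022
    V_init: 120
  la:
    Ees: 0.4
    V0: 10
    A: 0.3
    B: 0.025
    V_init: 50
  ra:
    Ees: 0.3
    V0: 10
    A: 0.25
    B: 0.022
    V_init: 50
septum:
  k_lv: 0.02
  k_rv: 0.02
  vref_lv: 60
  vref_rv: 60
valves:
- name: mitral
  from: la
  to: lv
  R: 0.006
  width: 0.1
- name: aortic
  from: lv
  to: ascending_aorta
  R: 0.008
  width: 0.1
- name: tricuspid
  from: ra
  to: rv
  R: 0.005
  width: 0.1
- name: pulmonary
  from: rv
  to: pulmonary_artery
  R: 0.006
  width: 0.1
nodes:
- name: ascending_aorta
  C: 0.4
  Vu: 60
  P0: 85
  role: arterial
- name: aortic_arch
  C: 0.3
  Vu: 40
  P0: 85
  role: arterial
- name: descending_thoracic_aorta
  C: 0.4
  Vu: 60
  P0: 84
  role: arterial
- name: thoracic_aorta
  C: 0.5
  Vu: 80
  P0: 83
  role: arterial
- name: upper_limbs_head
  C: 1.0
  Vu: 150
  P0: 80
  role: arterial
- name: coronary
  C: 0.05
  Vu: 10
  P0: 60
  role: coronary
- name: renal_hepatic
  C: 0.8
  Vu: 200
  P0: 80
  role: arterial
- name: splanchnic
  C: 1.0
  Vu: 300
  P0: 80
  role: arterial
- name: abdominal
  C: 0.4
  Vu: 120
  P0: 80
  role: arterial
- name: femoral_artery
  C: 0.6
  Vu: 180
  P0: 80
  role: arterial
- name: superior_vena_cava
  C: 12.0
  Vu: 500
  P0: 5
  role: venous
- name: femoral_vein
  C: 6.0
  Vu: 250
  P0: 5
  role: venous
- name: inferior_vena_cava
  C: 35.0
  Vu: 1700
  P0: 4
  role: venous
- name: pulmonary_artery
  C: 3.5
  Vu: 90
  P0: 15
  role: pulmonary
- name: pulmonary_veins
  C: 12.0
  Vu: 440
  P0: 9
  role: venous
links:
- name: asc_to_arch
  from: ascending_aorta
  to: aortic_arch
  R: 0.015
  L: 0.0002
  role: aortic
- name: arch_to_desc
  from: aortic_arch
  to: descending_thoracic_aorta
  R: 0.015
  L: 0.0002
  role: aortic
- name: thoracic
  from: descending_thoracic_aorta
  to: thoracic_aorta
  R: 0.04
  L: 0.0
  role: aortic
- name: arch_to_upper
  from: aortic_arch
  to: upper_limbs_head
  R: 0.15
  L: 0.0
  role: access
- name: upper_bed
  from: upper_limbs_head
  to: superior_vena_cava
  R: 2.089698028564
  L: 0.0
  role: bed
- name: svc_to_ra
  from: superior_vena_cava
  to: ra
  R: 0.11
  L: 0.0
  role: venous
- name: coronary_in
  from: ascending_aorta
  to: coronary
  R: 24.0
  L: 0.0
  role: coronary
- name: coronary_out
  from: coronary
  to: ra
  R: 3.0
  L: 0.0
  role: coronary
- name: to_renal
  from: thoracic_aorta
  to: renal_hepatic
  R: 0.1
  L: 0.0
  role: access
- name: renal_bed
  from: renal_hepatic
  to: inferior_vena_cava
  R: 1.79116973877
  L: 0.0
  role: bed
- name: to_splanchnic
  from: thoracic_aorta
  to: splanchnic
  R: 0.1
  L: 0.0
  role: access
- name: splanchnic_bed
  from: splanchnic
  to: inferior_vena_cava
  R: 2.189207458496
  L: 0.0
  role: bed
- name: to_abdominal
  from: thoracic_aorta
  to: abdominal
  R: 0.1
  L: 0.0
  role: access
- name: abdominal_bed
  from: abdominal
  to: inferior_vena_cava
  R: 7.214433670044
  L: 0.0
  role: bed
- name: to_femoral
  from: thoracic_aorta
  to: femoral_artery
  R: 0.12
  L: 0.0
  role: access
- name: leg_bed
  from: femoral_artery
  to: femoral_vein
  R: 2.189207458496
  L: 0.0
  role: bed
- name: fv_to_ivc
  from: femoral_vein
  to: inferior_vena_cava
  R: 0.6
  L: 0.0
  role: venous
- name: ivc_to_ra
  from: inferior_vena_cava
  to: ra
  R: 0.1
  L: 0.0
  role: venous
- name: pulmonary_bed
  from: pulmonary_artery
  to: pulmonary_veins
  R: 0.07
  L: 0.0002
  role: pulmonary
- name: pv_to_la
  from: pulmonary_veins
  to: la
  R: 0.015
  L: 0.0
  role: pulmonary
meta:
  knobs:
    ees_scale: 0.305532836914
    volume: 5506.0546875
    r_scale: 0.497547149658
    diastolic_scale: 1.6
    heart_rate: 90.0
  criteria:
    sbp: 55.224031355205
    svri: 1572.513199320796
    pcwp: 20.26123625327
    ci: 2.045635200251
  tuning_passes: 2
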