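# Reference (healthy) patient parameter set for the closed-loop model.
# All pressures mmHg, volumes mL, times s, resistances mmHg.s/mL,
# inertances mmHg.s^2/mL, compliances mL/mmHg.
#
# These values are stand-ins assembled from standard lumped-parameter
# modelling practice and calibrated so that the simulated healthy patient
# lands in the documented sanity band (CO 4.5-6 L/min, mean AoP 85-100 mmHg
# at HR 70). They are not a published patient parameterisation.

heart_rate: 70          # bpm
bsa: 1.8                # m^2
blood_volume: 5450      # mL, total (sets the initial volume distribution)

timing:
  ts_v_coef: 0.35       # ventricular systole Ts = ts_v_coef * sqrt(T)
  ts_a_coef: 0.17       # atrial systole   Ts = ts_a_coef * sqrt(T)
  av_delay: 0.16        # atrio-ventricular delay at T = 0.857 s, scaled ~ T
  av_delay_ref_period: 0.857
  peak_frac: 0.5

chambers:
  lv: {Ees: 2.50, V0: 15, A: 0.35, B: 0.027, V_init: 120}
  rv: {Ees: 0.55, V0: 15, A: 0.22, B: 0.022, V_init: 120}
  la: {Ees: 0.40, V0: 10, A: 0.30, B: 0.025, V_init: 50}
  ra: {Ees: 0.30, V0: 10, A: 0.25, B: 0.022, V_init: 50}

septum:
  k_lv: 0.02
  k_rv: 0.02
  vref_lv: 60
  vref_rv: 60

valves:
  - {name: mitral,    from: la, to: lv,  R: 0.006, width: 0.1}
  - {name: aortic,    from: lv, to: ascending_aorta, R: 0.008, width: 0.1}
  - {name: tricuspid, from: ra, to: rv,  R: 0.005, width: 0.1}
  - {name: pulmonary, from: rv, to: pulmonary_artery, R: 0.006, width: 0.1}

# Compliant nodes. P0 = initial pressure; Vu = unstressed volume.
# role: arterial / venous / pulmonary / coronary (venous nodes take up the
# blood-volume adjustment at initialisation).
nodes:
  - {name: ascending_aorta,           C: 0.40, Vu: 60,   P0: 85, role: arterial}
  - {name: aortic_arch,               C: 0.30, Vu: 40,   P0: 85, role: arterial}
  - {name: descending_thoracic_aorta, C: 0.40, Vu: 60,   P0: 84, role: arterial}
  - {name: thoracic_aorta,            C: 0.50, Vu: 80,   P0: 83, role: arterial}
  - {name: upper_limbs_head,          C: 1.00, Vu: 150,  P0: 80, role: arterial}
  - {name: coronary,                  C: 0.05, Vu: 10,   P0: 60, role: coronary}
  - {name: renal_hepatic,             C: 0.80, Vu: 200,  P0: 80, role: arterial}
  - {name: splanchnic,                C: 1.00, Vu: 300,  P0: 80, role: arterial}
  - {name: abdominal,                 C: 0.40, Vu: 120,  P0: 80, role: arterial}
  - {name: femoral_artery,            C: 0.60, Vu: 180,  P0: 80, role: arterial}
  - {name: superior_vena_cava,        C: 12.0, Vu: 500,  P0: 5,  role: venous}
  - {name: femoral_vein,              C: 6.0,  Vu: 250,  P0: 5,  role: venous}
  - {name: inferior_vena_cava,        C: 35.0, Vu: 1700, P0: 4,  role: venous}
  - {name: pulmonary_artery,          C: 3.5,  Vu: 90,   P0: 15, role: pulmonary}
  - {name: pulmonary_veins,           C: 12.0, Vu: 440,  P0: 9,  role: venous}

# Directed links; flow positive from -> to (direction of normal circulation).
# role "bed" marks the systemic microvascular resistances that the
# cardiogenic-shock tuner may scale.
links:
  - {name: asc_to_arch,      from: ascending_aorta,           to: aortic_arch,               R: 0.015, L: 0.0002, role: aortic}
  - {name: arch_to_desc,     from: aortic_arch,               to: descending_thoracic_aorta, R: 0.015, L: 0.0002, role: aortic}
  - {name: thoracic,         from: descending_thoracic_aorta, to: thoracic_aorta,            R: 0.040, L: 0,      role: aortic}  # RTHOR
  - {name: arch_to_upper,    from: aortic_arch,               to: upper_limbs_head,          R: 0.15,  L: 0,      role: access}  # cerebral/upper tap
  - {name: upper_bed,        from: upper_limbs_head,          to: superior_vena_cava,        R: 4.2,   L: 0,      role: bed}
  - {name: svc_to_ra,        from: superior_vena_cava,        to: ra,                        R: 0.110, L: 0,      role: venous}
  - {name: coronary_in,      from: ascending_aorta,           to: coronary,                  R: 24.0,  L: 0,      role: coronary}
  - {name: coronary_out,     from: coronary,                  to: ra,                        R: 3.0,   L: 0,      role: coronary}
  - {name: to_renal,         from: thoracic_aorta,            to: renal_hepatic,             R: 0.10,  L: 0,      role: access}
  - {name: renal_bed,        from: renal_hepatic,             to: inferior_vena_cava,        R: 3.6,   L: 0,      role: bed}
  - {name: to_splanchnic,    from: thoracic_aorta,            to: splanchnic,                R: 0.10,  L: 0,      role: access}
  - {name: splanchnic_bed,   from: splanchnic,                to: inferior_vena_cava,        R: 4.4,   L: 0,      role: bed}
  - {name: to_abdominal,     from: thoracic_aorta,            to: abdominal,                 R: 0.10,  L: 0,      role: access}
  - {name: abdominal_bed,    from: abdominal,                 to: inferior_vena_cava,        R: 14.5,  L: 0,      role: bed}
  - {name: to_femoral,       from: thoracic_aorta,            to: femoral_artery,            R: 0.12,  L: 0,      role: access}
  - {name: leg_bed,          from: femoral_artery,            to: femoral_vein,              R: 4.4,   L: 0,      role: bed}
  - {name: fv_to_ivc,        from: femoral_vein,              to: inferior_vena_cava,        R: 0.60,  L: 0,      role: venous}
  - {name: ivc_to_ra,        from: inferior_vena_cava,        to: ra,                        R: 0.100, L: 0,      role: venous}
  - {name: pulmonary_bed,    from: pulmonary_artery,          to: pulmonary_veins,           R: 0.07,  L: 0.0002, role: pulmonary}
  - {name: pv_to_la,         from: pulmonary_veins,           to: la,                        R: 0.015, L: 0,      role: pulmonary}
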