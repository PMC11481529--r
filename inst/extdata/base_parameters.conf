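name: base
kappa_a_nm2: 36300
kappa_c_nm2: 1440.0000000000002
kappa_v_nm2: 1130000
kappa_pa_nm2: 30
kappa_pc_nm2: 1440.0000000000002
kappa_pv_nm2: 19500.000000000004
kappa_e_nm2: 20
mu_a_Pa_s: 0.0022500000000000003
mu_c_Pa_s: 0.0022500000000000003
mu_v_Pa_s: 0.0022500000000000003
mu_pa_Pa_s: 0.00075000000000000002
mu_pc_Pa_s: 0.00075000000000000002
mu_pv_Pa_s: 0.00075000000000000002
mu_e_Pa_s: 0.00075000000000000002
phi_a: 0.0109
phi_c: 0.00231
phi_v: 0.019800000000000002
phi_pa: 0.0152
phi_pc: 0.00231
phi_pv: 0.027699999999999999
phi_e: 0.14000000000000001
C_a_per_Pa: 0.0001
C_c_per_Pa: 1e-08
C_v_per_Pa: 0.0001
C_pa_per_Pa: 1e-08
C_pc_per_Pa: 1e-08
C_pv_per_Pa: 1e-08
C_e_per_Pa: 1e-08
omega_a_c: 1.4500000000000001e-06
omega_c_v: 8.7499999999999992e-06
omega_c_pc: 8.4799999999999997e-10
omega_pa_pc: 9.9999999999999995e-07
omega_pc_pv: 9.9999999999999995e-07
omega_pa_e: 1.86e-07
omega_pv_e: 1.6500000000000001e-07
omega_pc_e: 1e-10
filtration_mode: pressure
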