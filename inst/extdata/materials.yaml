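# Soft-tissue material library for tongue-reconstruction simulation.
#
# Conventions:
#   * Ogden strain energy follows the FEBio definition
#       Psi = sum_i (c_i / m_i^2) * (lb1^m_i + lb2^m_i + lb3^m_i - 3) + k/2 (ln J)^2
#     with deviatoric principal stretches lb_a = J^(-1/3) lambda_a.
#   * Yeoh strain energy
#       Psi = sum_i c_i * (Ib1 - 3)^i + k/2 (ln J)^2,  Ib1 = J^(-2/3) I1.
#   * Prony relaxation function G(t) = 1 + sum_i gamma_i exp(-t / tau_i);
#     gamma_i dimensionless, tau_i in seconds.
#   * Stresses and moduli in kPa unless a field is suffixed _Pa, in which
#     case the loader converts to kPa (1 Pa = 1e-3 kPa).
materials:
  tongue:
    model: yeoh
    c_kPa: [1.037, 0.486]
    k_kPa: 100.0
    prony:
      tau_s: [0.05, 1.0, 20.0, 400.0]
      gamma: [39.0, 4.526, 4.895, 3.211]
  adipose:
    model: ogden
    c_kPa: [9.0]
    m: [6.0]
    k_kPa: 100.0
    prony:
      tau_s: [0.1, 1.0, 10.0]
      gamma: [4.428, 8.692, 0.738]
  forearm-skin-L1:
    model: ogden
    c1_kPa: 41.5
    c2_Pa: 1.39
    m: [1.223, 41.672]
    k_kPa: 200.0
    prony: &skin_prony
      tau_s: [0.3791, 4.1987, 6.9961, 180.02]
      gamma: [3.649, 0.452, 0.553, 0.627]
  forearm-skin-L2:
    model: ogden
    c1_kPa: 61.3
    c2_Pa: 4.38
    m: [7.059, 39.062]
    k_kPa: 200.0
    prony: *skin_prony
  forearm-skin-L3:
    model: ogden
    c1_kPa: 102.1
    c2_Pa: 5.20
    m: [7.660, 38.691]
    k_kPa: 200.0
    prony: *skin_prony
  thigh-skin-L1:
    model: ogden
    c1_kPa: 90.0
    c2_Pa: -10.0
    m: [13.431, 31.000]
    k_kPa: 200.0
    prony: *skin_prony
  thigh-skin-L2:
    model: ogden
    c1_kPa: 180.0
    c2_Pa: -60.0
    m: [14.531, 36.333]
    k_kPa: 200.0
    prony: *skin_prony
  thigh-skin-L3:
    model: ogden
    c1_kPa: 360.0
    c2_Pa: -120.0
    m: [13.839, 35.274]
    k_kPa: 200.0
    prony: *skin_prony
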