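# ncxdyn shipped default parameter set.
#
# Units: concentrations mM, time s, membrane potential mV (converted to volts
# once, at the Environment constructor), temperature K, fluxes mM/s.
#
# Provenance:
#   * Electrochemical cycle constants (KM_*, eta, ksat): Weber et al. 2001
#     cardiac NCX1 values, adopted unchanged (literature defaults).
#   * Allosteric gating constants (Kn, KCa/HCa, KNa/HNa, tau0/Ktau/Htau):
#     not available for astrocytic NCX; chosen so that the fast high-affinity
#     gate half-activates near 0.1 uM Ca, the slow deinactivation is relieved
#     near 1 uM Ca, and Na-dependent inactivation is already engaged at
#     resting astrocytic Na (15-20 mM) and saturated by ~25 mM (Matsuoka-type
#     behaviour). tau_min = 0.25 s is the high-Ca limit of the slow gate's
#     time constant.
#   * Jbar and the homeostasis constants set the flux scale and relaxation
#     times of a thin ER-free process; values give a monostable resting state
#     at physiological Na and a bistable low/high-Ca regime under Na loading
#     at -80 mV.
schema: ncxdyn-config-1
name: default
ncx:
  Jbar: 0.02        # mM/s, maximal NCX-mediated Ca flux scale
  KM_Cao: 1.3       # mM, Michaelis constant, external Ca
  KM_Nao: 87.5      # mM, external Na
  KM_Nai: 12.29     # mM, internal Na
  KM_Cai: 0.00359   # mM, internal Ca
  eta: 0.35         # energy-barrier position, dimensionless in [0,1]
  ksat: 0.27        # low-potential saturation factor, dimensionless
  Kn: 1.0e-4        # mM, half-activation of the fast gate n (0.1 uM)
  KCa: 1.0e-3       # mM, Ca half-relief of slow-gate inactivation (1 uM)
  HCa: 2.0          # Hill coefficient of Ca-dependent deinactivation
  KNa: 8.0          # mM, half-engagement of Na-dependent inactivation
  HNa: 4.0          # Hill coefficient of Na-dependent inactivation
  tau0: 10.0        # s, slow-gate time constant at low Ca
  Ktau: 1.0e-3      # mM, Ca half-acceleration of the slow gate (1 uM)
  Htau: 2.0         # Hill coefficient of tau_h(Ca)
  tau_min: 0.25     # s, slow-gate time constant at high Ca
environment:
  Ca_o: 2.0         # mM, extracellular Ca
  Na_o: 140.0       # mM, extracellular Na
  V_mV: -80.0       # mV, membrane potential
  T: 310.0          # K, absolute temperature
homeostasis:
  Ca_rest: 1.0e-4   # mM, resting internal Ca (0.1 uM)
  tau_Ca: 5.0       # s, lumped Ca equilibration time (pumps + buffering)
  Na_rest: 15.0     # mM, resting internal Na
  tau_Na: 20.0      # s, lumped Na equilibration time (Na/K-pump)
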