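# Long Na+ elevation protocol: sustained Na+ influx from t = 50 to 500 s at
# one of several amplitudes (the ladder below; quasi-steady plateaus of about
# 25, 30, 35 and 45 mM internal Na+ at the shipped homeostasis constants),
# with short Ca2+ probe pulses at t = 200 s (during the elevation) and
# t = 600 s (after it). The highest ladder amplitude is chosen to sustain a
# high-Ca state from the 200 s probe until Na+ offset.
schema: ncxdyn-protocol-1
name: fig2b
t_end: 800
na_window: [50, 500]
na_amplitudes: [0.5, 0.75, 1.0, 1.5]
ca_pulses:
  - {start: 200, duration: 5, amplitude: 2.0e-4}
  - {start: 600, duration: 5, amplitude: 2.0e-4}
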