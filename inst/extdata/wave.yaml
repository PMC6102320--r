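# One-dimensional thin-process wave protocol: a sealed 40 um segment at
# 0.35 um resolution. Sodium enters over the interval [0, 10] um on one side
# of the centre from t = 10 to 30 s; a short calcium pulse is applied to the
# central element (the 0.35-um interval around x = 0) at t = 20-22 s, while
# the Na+ influx maintains a standing side-to-side Na+ gradient. Anisotropy
# of the calcium spread is evaluated at measure_time.
schema: ncxdyn-protocol-1
name: wave
t_end: 45
measure_time: 28
grid:
  length: 40        # um
  dx: 0.35          # um
  D_Ca: 13          # um^2/s, effective (buffered) cytosolic Ca diffusion
  D_Na: 50          # um^2/s, effective cytosolic Na diffusion
  boundary: noflux
pulses:
  - {species: Na, start: 10, duration: 20, amplitude: 10,   x: [0, 10]}
  - {species: Ca, start: 20, duration: 2,  amplitude: 0.05, x: [-0.175, 0.175]}
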