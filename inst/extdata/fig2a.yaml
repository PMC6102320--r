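# Paired-pulse protocol: two short Na+ pulses of different amplitude, each
# accompanied by a short simultaneous Ca2+ pulse. Amplitudes are package
# presets chosen so that the joint response is visibly supra-linear while
# Na+ stays in the physiological-to-loaded range (transient rise ~10-25 mM).
# small_pulse_scale gives the amplitude factor of the companion "small pulse"
# protocol used for linearity checks of the allosteric-off control.
schema: ncxdyn-protocol-1
name: fig2a
t_end: 250
small_pulse_scale: 0.25
event_windows:
  - [40, 150]
  - [150, 250]
pulses:
  - {species: Na, start: 50, duration: 15, amplitude: 0.8}
  - {species: Ca, start: 50, duration: 5, amplitude: 1.0e-4}
  - {species: Na, start: 150, duration: 15, amplitude: 1.6}
  - {species: Ca, start: 150, duration: 5, amplitude: 1.0e-4}
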