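{
  "description": "Standard six-peak liver triglyceride spectrum. Chemical shifts are ppm offsets relative to the water resonance (negative = upfield of water); relative amplitudes are normalized at load time. Synthetic packaging of the widely used published liver model.",
  "peak_offsets_ppm": [0.60, -0.50, -1.94, -2.60, -3.40, -3.80],
  "relative_amplitudes": [0.048, 0.039, 0.004, 0.128, 0.693, 0.087]
}
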