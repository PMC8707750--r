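# frozen fingerprint of the image stack of the seed-123 internal trial
# (3 s window); guards against silent changes in the imaging pipeline
stack_fingerprint_golden <- structure(
  "stack_seed123_3s",
  values = c(-0.398069540157824, 0.584302341579833, -0.365945852845234,
             0.985265529124685, 0)
)
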