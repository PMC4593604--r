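# Ordered term list for the full-profile MANOVA (sequential SS: order
# matters). Well location and biological repeat enter as mains only.
terms:
  - well
  - bio_rep
  - strain
  - stage_dpf
  - trial_index
  - stimulus
  - strain:stage_dpf
  - strain:trial_index
  - strain:stimulus
  - stage_dpf:trial_index
  - stage_dpf:stimulus
  - trial_index:stimulus
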