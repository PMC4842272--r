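# Example module registry, in dependency order.
modules:
  - persistence.kb
  - bioaccumulation.kb
  - toxicity.kb
  - pbt.kb
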