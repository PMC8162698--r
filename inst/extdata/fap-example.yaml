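# FAP carcinogenesis: the built-in preset restated as an explicit override
# config -- germline point mutation in APC, hotspot region restricted to the
# classical codon 1250-1464 cluster.
preset: fap
genes:
  APC:
    n_hs: 600
germline: apc
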