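# Broad-antigen serological groups and multi-allele haplotypes.
# Miniature curated stand-in tables seeded from printed examples; editable.
broad_antigen:
  B22:
    - HLA-B*54:01
    - HLA-B*55:01
    - HLA-B*56:01
  A9:
    - HLA-A*23:01
    - HLA-A*24:02
  DR2:
    - HLA-DRB1*15:01
    - HLA-DRB1*16:01
haplotype:
  A1-B8-DR3:
    - HLA-A*01:01
    - HLA-B*08:01
    - HLA-DRB1*03:01
generic:
  - HLA class I
  - HLA class II
  - HLA linked
  - HLA associated
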