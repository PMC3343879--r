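# Named allele groups. B*35 alleles split by the peptide-binding preference
# at peptide position 9: Px alleles bind hydrophobic non-tyrosine residues,
# PY alleles bind tyrosine.
B35_Px:
  - B*35:02
  - B*35:03
B35_PY:
  - B*35:01
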