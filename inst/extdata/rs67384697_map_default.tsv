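# Default HLA-C allele -> rs67384697 (HLA-C 3'UTR G/del) mapping.
# Curated default covering common European four-digit HLA-C alleles,
# anchored by the complete LD (D' = 1) of C*06:02 with the deletion;
# replace with a full externally supplied table via read_deletion_map().
# Alleles absent from the table are imputed as 'unknown'.
allele	state
C*01:02	del
C*02:02	del
C*04:01	del
C*05:01	del
C*06:02	del
C*08:02	del
C*03:03	G
C*03:04	G
C*07:01	G
C*07:02	G
C*07:04	G
C*12:03	G
C*14:02	G
C*15:02	G
C*16:01	G
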