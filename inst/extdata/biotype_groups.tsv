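biotype	group
protein_coding	protein_coding
ncRNA	ncRNA
lncRNA	ncRNA
lincRNA	ncRNA
antisense	ncRNA
sense_intronic	ncRNA
sense_overlapping	ncRNA
bidirectional_promoter_lncRNA	ncRNA
3prime_overlapping_ncRNA	ncRNA
macro_lncRNA	ncRNA
miRNA	ncRNA
snoRNA	ncRNA
snRNA	ncRNA
scaRNA	ncRNA
scRNA	ncRNA
sRNA	ncRNA
rRNA	ncRNA
ribozyme	ncRNA
misc_RNA	ncRNA
Mt_rRNA	ncRNA
Mt_tRNA	ncRNA
pseudogene	pseudogene
processed_pseudogene	pseudogene
unprocessed_pseudogene	pseudogene
transcribed_processed_pseudogene	pseudogene
transcribed_unprocessed_pseudogene	pseudogene
transcribed_unitary_pseudogene	pseudogene
translated_processed_pseudogene	pseudogene
translated_unprocessed_pseudogene	pseudogene
unitary_pseudogene	pseudogene
polymorphic_pseudogene	pseudogene
rRNA_pseudogene	pseudogene
IG_C_pseudogene	pseudogene
IG_D_pseudogene	pseudogene
IG_J_pseudogene	pseudogene
IG_V_pseudogene	pseudogene
IG_pseudogene	pseudogene
TR_J_pseudogene	pseudogene
TR_V_pseudogene	pseudogene
other	other
processed_transcript	other
TEC	other
IG_C_gene	other
IG_D_gene	other
IG_J_gene	other
IG_LV_gene	other
IG_V_gene	other
TR_C_gene	other
TR_D_gene	other
TR_J_gene	other
TR_V_gene	other
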