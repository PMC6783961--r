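>infliximab_synthetic_HC synthetic IgG1-like heavy chain
QDPQNTGVFEDGNENLDMEHSVGQDSTKDLFVLMFCKNKHLREPNQDLEDKRSKLVLEAS
QARSEKLIDTDTIAYVEKRDPLSRMLNSEPCDEWGDITILKYFRALATEWSLCESIAKAW
ETKVVPQPLIATGFDKDEHKKEGSAPGQKLLESKINEAPQNGDTKTPAAIAYQREDKLSK
VASHVFLDRSPNDSGLEATASDGFVEENEEERVQRLTPGRVPTGQSYIWLKCPAPELLGG
HCEFEAVTQLLVAVMTPVIKADYSKKVAIHVYICNVDFTCQSETARRSSSDEVIDGSREI
QKLLAQSNPFTSLVTNTIRVGIQSYSKCVSRVDDTQTEDSVRQTAVFFIPTIDTSGTSFQ
TYKLKVKVEFYLEQRDLKTVAENTFYDLNCCKWAVHQTERDARCDLDLLTSPKLWLTHTQ
PTPHKGAFIDMAPVNSAYWRETRHSQAWE
>infliximab_synthetic_LC synthetic IgG1-like light chain
DYPVQPLGIDFFAYEADLPVEAVYECEIQFKEALESVQIREGRDTKLKLAAKKSMKTARW
LTEHSSYIDIEGVVTDLNVLGQKTVKRPEPEVLIPIPQLLNRGDRAGSYPKKLTRQEELN
EAVDTLKYLPGLKFFQRPKYLDAQSNSEEAYSHGKPGLLWLISAELVSFLKLFEVESQEA
VFQASEYWALKCYLDYPADVDRNWCHSTAAKRYV
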