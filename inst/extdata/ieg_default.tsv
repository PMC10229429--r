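gene
Fos
Fosb
Fosl1
Fosl2
Jun
Junb
Jund
Egr1
Egr2
Egr3
Egr4
Nr4a1
Nr4a2
Nr4a3
Arc
Npas4
Dusp1
Dusp2
Dusp4
Dusp5
Dusp6
Ier2
Ier3
Ier5
Ier5l
Btg1
Btg2
Atf3
Maff
Mafk
Gadd45a
Gadd45b
Gadd45g
Per1
Per2
Per3
Klf2
Klf4
Klf6
Klf10
Nfkbia
Nfkbid
Nfkbiz
Socs3
Cyr61
Ctgf
Trib1
Trib2
Sik1
Sik2
Sik3
Plk2
Plk3
Ppp1r15a
Rgs2
Rgs4
Sertad1
Srf
Tnfaip3
Tnfaip6
Dnajb1
Dnajb4
Dnajb5
Hspa1a
Hspa1b
Hspa5
Hspa8
Homer1
Bdnf
Pcsk1
Vgf
Scg2
Nptx1
Nptx2
Penk
Pdyn
Crh
Cartpt
Arl4d
Arl5b
Baz1a
Ccnl1
Coq10b
Crem
Csrnp1
Cxcl1
Fbxo33
Gem
Inhba
Irs2
Kcnf1
Lmna
Mcl1
Midn
Mest
Nab2
Nefm
Osgin2
Peli1
Ptgs2
Rasd1
Rasl11a
Rnd3
Slc2a3
Spty2d1
Stmn4
Tiparp
Tsc22d2
Ubc
Zbtb33
Zfp36
Zfp36l1
Zfp36l2
Rrad
Sgk1
Errfi1
Apold1
Bhlhe40
Bhlhe41
Rheb
Arl4a
Cdkn1a
Cebpb
Cebpd
Dnajb6
Eprs
Gpr3
Hes1
Id1
Id2
Id3
Ifit1
Il6
Jmjd1c
Kdm6b
Lingo1
Mbnl2
Ncoa7
Nfil3
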