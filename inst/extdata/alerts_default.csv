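alert_id,category,label,smarts
liver_proquinone,liver,quinones and pro-quinones (para amino/hydroxy/alkoxy benzene),"[$([NX3;!$([N+])]),$([OX2;!$([O-])])]c1ccc([$([NX3;!$([N+])]),$([OX2])])cc1"
dna_aromatic_nitro,dna_binder,aromatic nitro,"c[N+](=O)[O-]"
dna_aromatic_amine,dna_binder,aromatic amine (primary/secondary),"c[NX3;H2,H1;!$([N+])]"
dna_aromatic_azo,dna_binder,aromatic azo,"cN=Nc"
dart_nitroaromatic_ether,dart,aromatic nitro system ortho to aryl ether (reproductive toxicant),"[CX4][OX2]c1ccccc1[N+](=O)[O-]"
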