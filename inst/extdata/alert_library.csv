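id,smarts,mechanism,source,set
michael_acceptor_carbonyl,"[CX3]=[CX3][CX3]=[OX1]",Michael addition,protein-reactive-groups,B
michael_acceptor_nitrile,"[CX3]=[CX3]C#N",Michael addition,protein-reactive-groups,B
michael_acceptor_nitro,"[CX3]=[CX3][N+](=O)[O-]",Michael addition,protein-reactive-groups,B
quinone,"O=C1C=CC(=O)C=C1",Michael addition (quinone),protein-reactive-groups,B
aldehyde,"[CX3H1](=O)[#6]",Schiff base formation,protein-reactive-groups,B
alpha_dicarbonyl,"[CX3](=O)[CX3]=O",Schiff base formation,protein-reactive-groups,B
acyl_halide,"[CX3](=[OX1])[F,Cl,Br,I]",Acyl transfer,protein-reactive-groups,B
anhydride,"[CX3](=[OX1])[OX2][CX3]=[OX1]",Acyl transfer,protein-reactive-groups,B
primary_alkyl_halide,"[CH2X4][Cl,Br,I]",SN2 alkylation,protein-reactive-groups,B
sulfonate_ester,"[#6][SX4](=O)(=O)[OX2][#6]",SN2 alkylation,protein-reactive-groups,B
epoxide,"[OX2r3]1[#6r3][#6r3]1",SN2 ring opening,protein-reactive-groups,B
snar_halo_nitroarene_ortho,"[F,Cl,Br,I]c1ccccc1[N+](=O)[O-]",SNAr substitution,literature-mechanisms,C
snar_halo_nitroarene_para,"[F,Cl,Br,I]c1ccc(cc1)[N+](=O)[O-]",SNAr substitution,literature-mechanisms,C
isocyanate,"[NX2]=[CX2]=[OX1]",Carbamoylation,literature-mechanisms,C
isothiocyanate,"[NX2]=[CX2]=[SX1]",Thiocarbamoylation,literature-mechanisms,C
hydroperoxide,"[OX2][OX2H]",Radical / oxidative haptenation,literature-mechanisms,C
catechol,"[OX2H]c1ccccc1[OX2H]",Pre/pro-Michael oxidation,literature-mechanisms,C
hydroquinone,"[OX2H]c1ccc(cc1)[OX2H]",Pre/pro-Michael oxidation,literature-mechanisms,C
aryl_ester,"[CX3](=O)[OX2]c",Acyl transfer (activated ester),literature-mechanisms,C
alpha_halo_carbonyl,"[CX3](=O)[CH2X4][Cl,Br,I]",SN2 alkylation (activated),literature-mechanisms,C
aromatic_aldehyde,"[CX3H1](=O)c",Schiff base formation,literature-mechanisms,C
maleimide,"O=C1C=CC(=O)N1",Michael addition,literature-mechanisms,C
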