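(Anostraca,(Notostraca,(Laevicaudata,(Spinicaudata,(Cyclestherida,Cladocera)Cladoceromorpha)Onychocaudata)Diplostraca)Phyllopoda)Branchiopoda;
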