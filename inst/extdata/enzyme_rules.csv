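index,enzyme,ec,kind,substrate_pattern,product_pattern,res_add,link_add,constraint,target_terminal,substrate_printed,product_printed,constraint_printed,constraint_printed_machine,source_note
1,ManI,3.2.1.113,hydrolase,(M!a2M,(Ma,,,~M!a2Ma3Ma6,TRUE,(Ma2Ma,(Ma,~*2Ma3(...Ma6),none,"product/constraint cells garbled in source; curated reading enforces the printed constraint ""~*2Ma3(...Ma6)"" as: the target is not the a2-Man of the middle arm (the Ma3 branch of the core a6-Man), which row 2 removes in its own context; the printed reading leaves row 1 unconstrained"
2,ManI,3.2.1.113,hydrolase,(Ma3(M!a2Ma3(Ma6)Ma6)Mb4,(Ma3(Ma3(Ma6)Ma6)Mb4,,,,TRUE,(Ma3(Ma2Ma3(Ma6)Ma6),(Ma3(Ma3(Ma6)Ma6),,,"middle-arm a2-Man removal, gated on the core a3-Man being already fully trimmed (terminal); implicit common parent made explicit as Mb4"
3,ManII,3.2.1.114,hydrolase,(M!a3(Ma6)Ma6,(Ma6Ma6,,,GNb2|Ma3 & ~Gnbis,TRUE,(Ma3(Ma6)Ma6,(Ma6Ma6,GNb2 |Ma3 & ~Gnbis,,
4,ManII,3.2.1.114,hydrolase,(M!a6Ma6,(Ma6,,,GNb2|Ma3 & ~Gnbis & ~Ma3(M!a6)Ma6,TRUE,(Ma6Ma6,(Ma6,GNb2 |Ma3 & ~Gnbis,GNb2|Ma3 & ~Gnbis,"curated reading adds ~Ma3(M!a6)Ma6: the printed product ""(Ma6"" shows the parent Man becoming terminal, so the a3-linked sibling is already removed (row 3 acts before row 4)"
5,FUT8,2.4.1.68,transferase,GNb4GN!,GNb4(Fa6)GN,F,a6,GNb2|Ma3 & GNb2|Ma6 & ~Gnbis & ~Ab,FALSE,GNb4GN,GNb4(Fa6)GN,GNb2 |Ma3 & ~Gnbis & ~Ab,GNb2|Ma3 & ~Gnbis & ~Ab,"core fucosylation of the reducing-end GlcNAc; curated reading also requires GNb2 on the core a6-Man (biantennary acceptor): hybrid glycans with an unprocessed a6 arm are poor FUT8 acceptors, matching the per-enzyme specificity tables"
6,MGAT1,2.4.1.101,transferase,(M!a3(Ma3(Ma6)Ma6)Mb4,GNb2Ma3(Ma3(Ma6)Ma6)Mb4,GN,b2,~Ma2M,FALSE,(Ma33(Ma3(Ma6)Ma6)Mb4,(GNb2Ma3(Ma3(Ma6)Ma6)Mb4,,,"substrate cell printed ""(Ma33("" ; normalized per the product cell to the Man5 context; the added constraint ~Ma2M expresses that no a1-2 Man remains (Man5 exactly), mirroring the substMaxStruct field of the source framework"
7,MGAT2,2.4.1.143,transferase,(GNb2Ma3(M!a6)Mb4,GNb2Ma3(GNb2Ma6)Mb4,GN,b2,,TRUE,(GNb2|Ma3(Ma6)Mb4,(GNb2 |Ma3(GNb2Ma6)Mb4,,,"substrate cell garbled; read as: GNb2 on the core a3 branch, free (terminal) core a6-Man receives GNb2"
8,MGAT3,2.4.1.144,transferase,GNb2Ma3M!b4,GNb2Ma3(GNb4)Mb4,GN,b4,~Ab & ~Gnbis,FALSE,GNb2 |Ma3,GNb2 |Ma3(GNb4),~Ab & ~Gnbis,,bisecting GlcNAc added to the core beta-Man
9,MGAT4,2.4.1.145,transferase,(GNb2M!a3,(GNb2(GNb4)Ma3,GN,b4,~Gnbis,FALSE,(GNb2Ma3,(GNb2(GNb4)Ma3,~Gnbis,,
10,MGAT5,2.4.1.155,transferase,(GNb2M!a6,(GNb2(GNb6)Ma6,GN,b6,~Gnbis,FALSE,(GNb2Ma6,(GNb2(GNb6)Ma6,~Gnbis,,
11,iGnT,2.4.1.149,transferase,(A!b4GN,(GNb3Ab4GN,GN,b3,~_Ma3|Mb4,FALSE,(Ab4GN,(GNb3Ab4GN,~_Ma3 |Mb4,,"""_"" read as: the action target must not lie on the core a3-Man branch of Mb4"
12,b4GalT,2.4.1.38,transferase,(GN!,(Ab4GN,A,b4,~Gnbis,FALSE,(GN,(Ab4GN,(~*GNb4)(...Ma6)Mb4,,"constraint cell ""(~*GNb4)(...Ma6)Mb4"" read as: no residue attached b1-4 to the core beta-Man (no bisecting GlcNAc)"
13,a3SiaT,2.4.99.6,transferase,(A!b4GN,(NNa3Ab4GN,NN,a3,,FALSE,(Ab4GN,(NNa3Ab4GN,,,
14,IGNT,2.4.1.150,transferase,(Ab4GNb3A!b,(Ab4GNb3(GNb6)Ab,GN,b6,,FALSE,(Ab4GNb3Ab,(Ab4GNb3(GNb6)Ab,,,
15,a6SiaT,2.4.99.1,transferase,(A!b4GN,(NNa6Ab4GN,NN,a6,,FALSE,(Ab4GN,(NNa6Ab4GN,,,
16,b3GalT1,2.4.1.62,transferase,(GN!,(Ab3GN,A,b3,~Gnbis,FALSE,(GN,(Ab3GN,(~*GNb4)(...Ma6)Mb4,,constraint normalized as in row 12
17,FUT3,2.4.1.65,transferase,Ab3GN!b,Ab3(Fa4)GNb,F,a4,(Ab3*! or (Fa2Ab3*! or (NNa3Ab3*!,FALSE,Ab3GNb,Ab3(Fa4)GNb,(Ab3* or (Fa2Ab3* or (NNa3Ab3*),,"Lewis a / sialyl-Lewis a context: the type-1 Gal of the target antenna is uncapped, Fuc(a1-2)-capped or Neu5Ac(a2-3)-capped"
18,FUT3,2.4.1.65,transferase,(...Ab4GN!b,Fa3(Ab4)GNb,F,a3,(*Ab4*! or (*Fa2Ab4*! or (*NNa3Ab4*!,FALSE,(...Ab4GNb,(Fa3(...Ab4)GNb,(*Ab4 or (*Fa2Ab4 or (*NNa3Ab4),,"Lewis x context as transcribed; the type-2 Gal of the target antenna carries a cap (see row 21, flagged as duplicated-looking in the source)"
19,FUT1,2.4.1.69,transferase,(A!b3GNb,(Fa2Ab3GNb,F,a2,,FALSE,(Ab3GNb,(Fa2Ab3GNb,,,
20,FUT1,2.4.1.69,transferase,(A!b4GNb,(Fa2Ab4GNb,F,a2,,FALSE,(Ab4GNb,(Fa2Ab4GNb,,,
21,a3FucT,2.4.1.152,transferase,(...Ab4GN!b,Fa3(Ab4)GNb,F,a3,(*Ab4*! or (*Fa2Ab4*!,FALSE,(...Ab4GNb,(Fa3(...Ab4)GNb,(*Ab4 or (*Fa2Ab4,,
22,GalNAcT-A,2.4.1.40,transferase,(Fa2A!b,(Fa2(ANa3)Ab,AN,a3,,FALSE,(Fa2Ab,(Fa2(ANa3)Ab,,,blood-group A synthase
23,GalT-B,2.4.1.37,transferase,(Fa2A!b,(Fa2(Aa3)Ab,A,a3,,FALSE,(Fa2Ab,(Fa2(Aa3)Ab,,,blood-group B synthase
24,b3GALT6,2.4.1.134,transferase,A!b4GN,Ab3Ab4GN,A,b3,,FALSE,Ab4GN,Ab3Ab4GN,,,
25,b3GALT6,2.4.1.134,transferase,A!b4A,Ab3Ab4A,A,b3,,FALSE,Ab4A,Ab3Ab4A,,,
26,c1GALT1,2.4.1.122,transferase,AN!,Ab3AN,A,b3,,FALSE,AN,Ab3AN,,,
27,st3galI,2.4.99.4,transferase,(A!b3GN,(NNa3Ab3GN,NN,a3,,FALSE,(Ab3GN,(NNa3Ab4GN,,,"product cell printed ""(NNa3Ab4GN"" for substrate ""(Ab3GN""; inconsistent as printed, encoded as Neu5Ac(a2-3) onto the type-1 Gal; overlaps row 13 (a3SiaT), flagged"
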