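peak_no,delta_ppm,multiplicity,metabolite,moiety
1,0.9587,d,Valine,"γ-CH3/γ'-CH3 (isopropyl methyls)"
2,1.0000,s,Isoleucine (tentative),"δ-CH3 (terminal methyl)"
3,1.0521,d,Valine,"γ-CH3/γ'-CH3 (isopropyl methyls)"
4,1.0955,,Unassigned,
5,1.3061,d,Threonine,"γ-CH3"
6,1.3390,d,Lactate,"β-CH3"
7,1.4315,m,Lysine (tentative),"Side-chain CH2 envelope (β/γ/δ overlap)"
8,1.4715,d,Alanine,"β-CH3"
9,1.6708,m,Arginine (tentative),"β/γ-CH2 (side-chain methylenes)"
10,1.7280,m,Lysine,"δ-CH2 (side-chain methylene)"
11,1.9052,s,Acetate,"CH3"
12,2.0630,s,N-acetylglucosamine (putative),"NAc-CH3 (acetamide methyl)"
13,2.0816,m,Glutamate,"β-CH2"
14,2.1488,m,Glutamine,"β-CH2"
15,2.2327,s,Unassigned,
16,2.3570,t,Glutamate,"γ-CH2"
17,2.4600,,Glutamine (tentative),"γ-CH2"
18,2.6797,s,Methylamine,"CH3-NH3+ (methyl)"
19,2.7913,s,Trimethylamine (tentative),"N(CH3)3"
20,2.9100,m,Choline (tentative)/methylamine region,"N-methyl region (overlap)"
21,3.0362,t,Lysine,"ε-CH2 (adjacent to NH3+)"
22,3.1273,t,Histidine,"β-CH2"
23,3.2040,s,Choline/choline derivatives,"N+(CH3)3 (trimethylammonium)"
24,3.2298,s,Betaine,"N+(CH3)3"
25,3.2488,(s),Trimethylamine oxide (TMAO),"N+(CH3)3 (amine oxide)"
26,3.2665,t,Taurine,"CH2-NH3+"
27,3.3074,s,"3,7-Dimethyluric acid (putative)","N-CH3 (xanthine/urate scaffold)"
28,3.3539,s,Methanol,"CH3OH"
29,3.3813,,Methanol (shoulder)/unassigned,
30,3.4100,s,Unassigned,
31,3.5042,m,Unassigned,"CH2-O (carbohydrate/ribose/glycerol-type)"
32,3.5101,m,Choline-related (probable),"CH2-O (choline moiety)"
33,3.5648,s,Glycine,"α-CH2"
34,3.7611,t,Lysine,"Hα (backbone CH)"
35,3.7979,,Alanine,"Hα (backbone CH)"
36,3.8532,m,Trehalose/carbohydrate (putative),"Sugar ring CH envelope"
37,3.9000,,Betaine (tentative),"CH2-COO-"
38,3.9323,s,Creatine,"CH2 (adjacent to guanidino system)"
39,3.9800,,Unassigned,
40,4.3665,s,Trigonelline,"N-CH3 (quaternary N-methyl)"
41,5.7910,d/m,Uridine,"H-5 (pyrimidine CH)"
42,5.9940,d/m,Pyrimidine nucleoside (uridine/cytidine-like),"H-5 (pyrimidine CH)"
43,6.1000,d,Purine riboside/ribonucleotide (inosine/IMP-like),"H-1' (ribose anomeric proton)"
44,6.8000,s,"Phenolic aromatic (vanillic/vanillin-like, putative)","Aromatic ring CH"
45,6.9070,d,Tyrosine,"H-3,5 (AA'BB' ring CH)"
46,7.1260,s,Histidine,"Imidazole CH (H-δ2)"
47,7.1850,d,Tyrosine,"H-2,6 (AA'BB' ring CH)"
48,7.2662,m,Phenylalanine,"Aromatic ring CH envelope"
49,7.2870,d/m,Tryptophan,"Indole ring CH (H-5)"
50,7.3250,m,Phenylalanine (tentative),"Aromatic ring CH envelope"
51,7.3410,s,Imidazole,"Ring CH (H-4/H-5)"
52,7.4160,m,Phenylalanine,"Aromatic ring CH envelope"
53,7.5340,d/m,Tryptophan,"Indole ring CH (H-7)"
54,7.5500,S,Uracil,"H-6 (pyrimidine CH)"
55,7.6850,s,Unassigned,"Aromatic CH (unknown)"
56,7.7260,s/m,Xanthine and/or Tryptophan,"Purine H-8 and/or indole aromatic CH"
57,7.7730,s,Anserine (putative),"Imidazole CH (histidine-derived)"
58,7.8510,s,N-acetyl-L-histidine (putative),"Imidazole CH"
59,7.8620,d,Uridine,"H-6 (pyrimidine CH)"
60,7.8820,s,Unassigned,"Aromatic CH (unknown)"
61,7.9730,t,Kynurenine-like (HSQC-consistent; downfield-shifted),"Aromatic ring CH"
62,8.0000,s,Hypoxanthine,"H-8 (purine CH)"
63,8.0283,d,Kynurenine,
64,8.0840,m,Trigonelline (reported),"Pyridinium ring CH"
65,8.2351,s,Purine riboside/ribonucleotide (inosine/IMP-like),"Purine H-8 (ring CH)"
66,8.2710,s,Imidazole,"Ring CH (H-4/H-5)"
67,8.3460,s,Purine riboside/ribonucleotide (inosine/IMP-like),"Purine H-2 (ring CH)"
68,8.5454,t,Kynurenine,"Pyridinium ring CH (overlapped)"
69,8.5936,s,Adenine nucleotide (AMP-like),"Adenine H-8 (purine CH)"
70,8.6998,m,Kynurenine,
71,8.8380,m,Trigonelline,"Pyridinium ring CH (downfield member)"
72,9.1260,s/m,Trigonelline,"Pyridinium ring CH (most downfield)"
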