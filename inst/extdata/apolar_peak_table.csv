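peak_no,delta_ppm,moiety,lipid_class,assignment
1,0.6803,"Sterol methyl (C18-CH3)","Sterols (cholesterol-like)","Sterol angular methyl (18-CH3)"
2,0.8806,"Terminal -CH3","FA in TAG/DAG/MAG/PL","Terminal methyl of fatty acyl chains (major lipid methyl envelope)"
3,0.9739,"ω-3 terminal -CH3","ω-3 PUFA in TAG/PL","ω-3 methyl (EPA/DHA-type chains)"
4,1.1150,"Aliphatic methyl/methylene","Sterols/FA (minor)","Minor aliphatic resonance (sterol methyls/overlapping lipid methylenes)"
5,1.2563,"-(CH2)n-","FA in TAG/DAG/MAG/PL","Bulk methylene envelope of fatty acyl chains"
6,1.3022,"-(CH2)n-","FA in TAG/DAG/MAG/PL","Bulk methylene envelope of fatty acyl chains"
7,1.4978,"Aliphatic -CH2-","TAG/PL (overlap)","Mixed aliphatic region"
8,1.6032,"β-CH2 to C=O","TAG/PL (non-DHA enriched)","β-CH2 to carbonyl (acyl groups; general lipid region)"
9,1.6757,"β-CH2 to C=O","PUFA-enriched TAG/PL","β-CH2 to carbonyl (often increases with PUFA-rich acyl distributions)"
10,1.8282,"Aliphatic/allylic overlap","TAG/PL/sterols","Minor overlapped aliphatic signal"
11,2.0202,"Allylic -CH2-CH=CH-","UFA in TAG/PL","Allylic methylene (unsaturated acyl chains)"
12,2.0780,"Allylic -CH2-CH=CH-","UFA in TAG/PL","Allylic methylene (unsaturated acyl chains)"
13,2.3079,"α-CH2 to C=O","TAG/PL/FFA","α-CH2 to carbonyl (acyl groups; broad F1-like region)"
14,2.3869,"α-CH2 to C=O (DHA-sensitive window)","DHA-containing TAG/PL and/or DHA (FFA)","DHA marker window (α-CH2 near carbonyl for DHA acyl groups/DHA region)"
15,2.4764,"Minor","Trace/unknown","Unassigned weak resonance"
16,2.7722,"Bis-allylic -CH=CH-CH2-CH=CH-","PUFA (ω-6/ω-3)","Bis-allylic methylene (PUFA)"
17,2.8094,"Bis-allylic -CH=CH-CH2-CH=CH-","PUFA (ω-6/ω-3)","Bis-allylic methylene (PUFA)"
18,2.8424,"Bis-allylic -CH=CH-CH2-CH=CH-","PUFA (ω-6/ω-3)","Bis-allylic methylene (PUFA)"
19,3.1409,"Headgroup methylenes","PL (PE/others)","Putative ethanolamine-related methylenes (PE-type region)"
20,3.3273,"N+(CH3)3","PL (PC/SM)","Choline trimethylammonium (PC/SM total choline region)"
21,3.4892,"Residual solvent proton(s)","","MeOH trace (residual solvent/contamination)"
22,3.5343,"Sterol H-3 (-CHOH)","Sterols","Sterol C3 proton (H-3, cholesterol-like)"
23,3.7723,"-CH2-O- (backbone)","DG/MG and/or PL","Glycerol/PL backbone region (overlap: DG/MG glycerol + PL backbone methylenes)"
24,3.9490,"-CH2-O-P- (phosphodiester-linked methylene)","PL","Phospholipid backbone region (CH2O-P/adjacent backbone methylenes)"
25,4.1673,"-CH2-O- (glycerol)","DG/MG and/or PL","Glycerol backbone methylenes (MG/DG) with possible PL overlap"
26,4.2848,"-CH2-O- (glycerol)","DG (1,2-DG) and/or PL","DG/PL backbone methylenes (often used for partial glycerides; overlaps PL)"
27,4.3841,"-CH2-CH2-N+(CH3)3 (choline methylenes)","PL (PC/SM)","Choline methylene region (PC/SM headgroup side-chain)"
28,5.2784,"sn-2 glycerol -CH-O-","TAG (± overlap)","TAG glycerol sn-2 CH"
29,5.3654,"Olefinic -CH=CH- (± sterol H-6 overlap)","UFA in TAG/PL + sterols","Olefinic protons of unsaturated acyl chains; can overlap sterol H-6"
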