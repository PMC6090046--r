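index,name,hemisphere,lobe,homolog
1,Precentral_L,L,central,2
2,Precentral_R,R,central,1
3,Frontal_Sup_L,L,frontal,4
4,Frontal_Sup_R,R,frontal,3
5,Frontal_Sup_Orb_L,L,frontal,6
6,Frontal_Sup_Orb_R,R,frontal,5
7,Frontal_Mid_L,L,frontal,8
8,Frontal_Mid_R,R,frontal,7
9,Frontal_Mid_Orb_L,L,frontal,10
10,Frontal_Mid_Orb_R,R,frontal,9
11,Frontal_Inf_Oper_L,L,frontal,12
12,Frontal_Inf_Oper_R,R,frontal,11
13,Frontal_Inf_Tri_L,L,frontal,14
14,Frontal_Inf_Tri_R,R,frontal,13
15,Frontal_Inf_Orb_L,L,frontal,16
16,Frontal_Inf_Orb_R,R,frontal,15
17,Rolandic_Oper_L,L,central,18
18,Rolandic_Oper_R,R,central,17
19,Supp_Motor_Area_L,L,central,20
20,Supp_Motor_Area_R,R,central,19
21,Olfactory_L,L,frontal,22
22,Olfactory_R,R,frontal,21
23,Frontal_Sup_Medial_L,L,frontal,24
24,Frontal_Sup_Medial_R,R,frontal,23
25,Frontal_Med_Orb_L,L,frontal,26
26,Frontal_Med_Orb_R,R,frontal,25
27,Rectus_L,L,frontal,28
28,Rectus_R,R,frontal,27
29,Insula_L,L,insula_subcortical,30
30,Insula_R,R,insula_subcortical,29
31,Cingulum_Ant_L,L,limbic,32
32,Cingulum_Ant_R,R,limbic,31
33,Cingulum_Mid_L,L,limbic,34
34,Cingulum_Mid_R,R,limbic,33
35,Cingulum_Post_L,L,limbic,36
36,Cingulum_Post_R,R,limbic,35
37,Hippocampus_L,L,insula_subcortical,38
38,Hippocampus_R,R,insula_subcortical,37
39,ParaHippocampal_L,L,limbic,40
40,ParaHippocampal_R,R,limbic,39
41,Amygdala_L,L,insula_subcortical,42
42,Amygdala_R,R,insula_subcortical,41
43,Calcarine_L,L,occipital,44
44,Calcarine_R,R,occipital,43
45,Cuneus_L,L,occipital,46
46,Cuneus_R,R,occipital,45
47,Lingual_L,L,occipital,48
48,Lingual_R,R,occipital,47
49,Occipital_Sup_L,L,occipital,50
50,Occipital_Sup_R,R,occipital,49
51,Occipital_Mid_L,L,occipital,52
52,Occipital_Mid_R,R,occipital,51
53,Occipital_Inf_L,L,occipital,54
54,Occipital_Inf_R,R,occipital,53
55,Fusiform_L,L,temporal,56
56,Fusiform_R,R,temporal,55
57,Postcentral_L,L,central,58
58,Postcentral_R,R,central,57
59,Parietal_Sup_L,L,parietal,60
60,Parietal_Sup_R,R,parietal,59
61,Parietal_Inf_L,L,parietal,62
62,Parietal_Inf_R,R,parietal,61
63,SupraMarginal_L,L,parietal,64
64,SupraMarginal_R,R,parietal,63
65,Angular_L,L,parietal,66
66,Angular_R,R,parietal,65
67,Precuneus_L,L,parietal,68
68,Precuneus_R,R,parietal,67
69,Paracentral_Lobule_L,L,central,70
70,Paracentral_Lobule_R,R,central,69
71,Caudate_L,L,insula_subcortical,72
72,Caudate_R,R,insula_subcortical,71
73,Putamen_L,L,insula_subcortical,74
74,Putamen_R,R,insula_subcortical,73
75,Pallidum_L,L,insula_subcortical,76
76,Pallidum_R,R,insula_subcortical,75
77,Thalamus_L,L,insula_subcortical,78
78,Thalamus_R,R,insula_subcortical,77
79,Heschl_L,L,temporal,80
80,Heschl_R,R,temporal,79
81,Temporal_Sup_L,L,temporal,82
82,Temporal_Sup_R,R,temporal,81
83,Temporal_Pole_Sup_L,L,temporal,84
84,Temporal_Pole_Sup_R,R,temporal,83
85,Temporal_Mid_L,L,temporal,86
86,Temporal_Mid_R,R,temporal,85
87,Temporal_Pole_Mid_L,L,temporal,88
88,Temporal_Pole_Mid_R,R,temporal,87
89,Temporal_Inf_L,L,temporal,90
90,Temporal_Inf_R,R,temporal,89
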