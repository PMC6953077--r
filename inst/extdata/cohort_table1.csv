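patient_id,age_group,histology,er,pr,her2,ki67_pct,tdim_pre_cm,tdim_post_cm,yptn
52,le40,ductal,pos,pos,neg,5,6.0,3.5,ypT2N0
84,gt40,lobular,pos,neg,neg,5,8.0,0.0,ypT0N0
67,gt40,mixed,pos,pos,neg,10,8.3,18.0,ypT4N3
20,le40,ductal,pos,pos,neg,10,6.0,6.0,ypT4N2
71,le40,in_situ_component,pos,pos,neg,10,7.6,4.5,ypT2N3
66,gt40,ductal,pos,pos,neg,60,11.0,0.8,ypT1bN0
68,gt40,ductal,pos,pos,neg,80,8.0,5.4,ypT3N2
33,gt40,ductal,pos,pos,neg,20,6.0,0.6,ypT1bN2
64,le40,ductal,pos,pos,neg,20,8.0,1.8,ypT1cN1
54,gt40,ductal,pos,pos,neg,20,9.0,8.3,ypT3N0
19,gt40,ductal,pos,pos,neg,20,7.0,8.0,ypT3N2
37,le40,ductal,pos,pos,neg,20,6.5,6.5,ypT3N1
58,le40,ductal,pos,neg,neg,30,10.0,11.0,ypT4N3
7,gt40,ductal,pos,pos,neg,30,7.8,1.5,ypT1cN3
79,le40,ductal,pos,pos,neg,70,5.2,0.0,ypT0N0
9,gt40,ductal,neg,pos,neg,70,4.0,4.4,ypT2N0
6,gt40,ductal,neg,pos,neg,80,6.0,7.8,ypT4N2
73,le40,ductal,pos,pos,neg,80,8.0,5.8,ypT3N2
63,gt40,ductal,pos,pos,neg,90,6.5,0.6,ypT1bN0
80,le40,ductal,pos,pos,neg,90,6.1,2.8,ypT4Nx
81,le40,ductal,pos,neg,nd,100,6.4,5.0,ypT2N1
30,gt40,lobular,pos,pos,neg,,6.0,5.5,ypT3N1
56,le40,ductal,pos,pos,pos,,14.0,6.8,ypT3N1
62,gt40,ductal,pos,pos,neg,10,6.0,2.0,ypT1cN0
55,gt40,ductal,pos,pos,neg,10,5.5,6.3,ypT4N2
99,gt40,ductal,pos,pos,pos,10,12.0,0.8,ypT4N0
17,gt40,ductal,pos,neg,pos,20,8.0,9.0,ypT4N2
69,le40,ductal,pos,neg,neg,90,5.5,9.0,ypT3N3
18,gt40,ductal,pos,neg,neg,90,4.0,1.7,ypT1N2
11,gt40,ductal,pos,pos,pos,,7.0,2.2,ypT2N2
72,gt40,ductal,pos,pos,pos,,5.5,0.0,ypT0N1
59,gt40,ductal,neg,neg,pos,60,6.0,5.8,ypT3N1
49,gt40,ductal,neg,neg,pos,90,8.0,0.0,ypT1miN0
60,le40,ductal,neg,neg,neg,,3.5,0.0,ypT0N0
44,le40,ductal,neg,neg,pos,100,5.4,2.0,ypT1cN0
70,gt40,other,neg,neg,neg,40,5.1,4.5,ypT2N2
75,gt40,ductal,neg,neg,neg,60,7.0,7.5,ypT4N3
51,le40,ductal,neg,neg,pos,80,8.9,4.5,ypT4N1
38,gt40,ductal,neg,neg,neg,90,5.2,1.0,ypT1bN0
36,le40,ductal,neg,neg,neg,90,6.5,4.0,ypT4N3
76,gt40,ductal,neg,neg,neg,90,8.5,0.0,ypTisN0
45,gt40,lobular,neg,neg,neg,,7.5,4.0,ypT4N3
13,le40,ductal,neg,neg,neg,,6.5,4.2,ypT2N1
61,gt40,ductal,neg,neg,neg,100,5.5,0.3,ypT1aN0
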