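id,r1_group,ar_label,ic50_um,printed_activity,is_test
1,Propyl,Ar01,16.17,-1.21,FALSE
2,Propyl,Ar02,0.13,0.89,FALSE
3,Propyl,Ar03,0.06,0.89,FALSE
4,Propyl,Ar04,6.45,-0.81,FALSE
5,Propyl,Ar05,0.018,1.74,FALSE
6,Propyl,Ar06,5.12,-0.71,FALSE
7,Propyl,Ar07,2.05,-0.31,FALSE
8,Propyl,Ar08,1.06,-0.03,TRUE
9,Propyl,Ar09,7.36,-0.87,FALSE
10,Propyl,Ar10,0.80,0.10,TRUE
11,Propyl,Ar11,0.94,0.03,FALSE
12,Benzyl,Ar12,3.11,-0.49,FALSE
13,Benzyl,Ar13,0.071,1.15,FALSE
14,Benzyl,Ar14,0.022,1.66,FALSE
15,Benzyl,Ar15,12.10,-1.08,FALSE
16,Benzyl,Ar16,3.33,-0.52,TRUE
17,Benzyl,Ar17,10.67,-1.03,FALSE
18,Benzyl,Ar18,24.39,-1.39,FALSE
19,Benzyl,Ar19,8.85,-0.95,FALSE
20,Cyclopentyl,Ar20,7.26,-0.86,FALSE
21,Cyclopentyl,Ar21,0.25,0.60,FALSE
22,Cyclopentyl,Ar22,0.073,1.14,TRUE
23,Cyclopentyl,Ar23,1.58,-0.20,FALSE
24,Cyclopentyl,Ar24,0.026,1.59,TRUE
25,Cyclopentyl,Ar25,4.08,-0.61,FALSE
26,Cyclopentyl,Ar26,0.55,0.26,FALSE
27,Cyclopentyl,Ar27,1.71,-0.23,FALSE
28,Cyclopentyl,Ar28,1.68,-0.52,TRUE
29,Cyclopentyl,Ar29,0.31,0.51,FALSE
30,Cyclopentyl,Ar30,3.06,-0.49,FALSE
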