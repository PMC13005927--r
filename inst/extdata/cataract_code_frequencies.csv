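code,description,f_a,f_b,printed_ratio
E08.36,Diabetes mellitus due to underlying condition with diabetic cataract,23,0,3.10
E10.36,Type 1 diabetes mellitus with diabetic cataract,92,117,0.75
E11.36,Type 2 diabetes mellitus with diabetic cataract,3065,2996,0.96
H26.40,Unspecified secondary cataract,561,1144,0.46
H26.411,Soemmering's ring right eye,11,1,1.79
H26.491,Other secondary cataract right eye,3044,771,3.67
H26.492,Other secondary cataract left eye,3129,741,3.93
H26.493,Other secondary cataract bilateral,3952,636,5.76
H26.499,Other secondary cataract unspecified eye,70,0,7.51
H26.8,Other specified cataract,526,1323,0.38
H26.9,Unspecified cataract,16704,15786,0.99
H59.021,Cataract fragments in eye following cataract surgery right eye,47,14,2.23
H59.022,Cataract fragments in eye following cataract surgery left eye,78,10,4.13
H59.029,Cataract fragments in eye following cataract surgery unspecified eye,1,72,0.13
Z96.1,Presence of intraocular lens,35888,44526,0.76
Z98.41,Cataract extraction status right eye,3950,199,17.79
Z98.42,Cataract extraction status left eye,3723,195,17.10
Z98.49,Cataract extraction status unspecified eye,622,112,4.87
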