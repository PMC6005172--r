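gene	sowh_p	au_p_bootstrap	au_p_manual
ML00555a	0.001	4.00e-45	7.00e-06
ML49231a	0.001	2.00e-44	7.00e-103
ML092610a	0.001	2.00e-31	4.00e-68
ML005129a	0.001	1.00e-04	6.00e-06
ML00955a	0.001	0.021	0.002
ML02771a	0.001	0.023	0.029
ML42441a	0.001	0.047	0.022
ML177319a	0.001	0.226	0.042
ML120721a	0.001	0.48	0.245
ML049014a	0.985	0.862	0.604
ML070218a	0.262	0.849	0.361
ML102910a	0.229	0.719	0.255
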