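case	chrom	start	end
25	1	182537598	197949082
129	1	61620929	76755163
147	2	79211952	89129064
147	2	95341387	128342675
147	2	22170065	68067589
944	2	155368924	174708199
11	3	176695771	189044675
947	3	72016624	77325155
947	3	133992740	149438082
1101	5	77967561	94997034
169	7	90678991	109653423
346	7	29374797	40699189
833	8	70942228	94406882
505	9	108394893	122047673
76	10	112544654	124513498
776	10	72616063	91065521
569	11	83339664	95895139
633	11	11473107	32068176
628	11	45853773	51550787
628	11	71543708	76752248
674	12	257936	22766988
284	12	69859080	84755083
430	12	78736693	92566637
407	13	75078803	92192744
312	14	36397727	64565981
204	16	89560	12548052
47	17	53332043	65633600
584	18	9990161	15143714
584	18	18540834	36061962
907	20	29510307	42027093
907	20	17489413	26266313
209	22	26504838	40021614
443	22	37977281	51157531
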