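energy_mev	f_compton
0.01	0.0187636
0.0111458	0.0208156
0.0124229	0.0230803
0.0138464	0.0255771
0.0154329	0.0283264
0.0172012	0.0313501
0.0191722	0.0346708
0.0213689	0.0383121
0.0238174	0.0422982
0.0265464	0.0466539
0.0295882	0.0514041
0.0329784	0.0565733
0.0367571	0.0621855
0.0409688	0.0682636
0.0456631	0.0748287
0.0508952	0.0818999
0.0567269	0.0894933
0.0632267	0.0976218
0.0704713	0.106294
0.078546	0.115515
0.087546	0.125284
0.0975771	0.135597
0.108758	0.146444
0.121219	0.157809
0.135109	0.169674
0.15059	0.182015
0.167844	0.194807
0.187076	0.20802
0.208512	0.221623
0.232403	0.235583
0.259032	0.249866
0.288713	0.26444
0.321794	0.279267
0.358665	0.294314
0.399762	0.309543
0.445567	0.324916
0.496621	0.340396
0.553524	0.355942
0.616948	0.371514
0.687639	0.387068
0.766429	0.402563
0.854248	0.417956
0.952129	0.433205
1.06123	0.448271
1.18282	0.463115
1.31835	0.477703
1.46941	0.492002
1.63778	0.505986
1.82544	0.51963
2.0346	0.532915
2.26772	0.545825
2.52756	0.558348
2.81718	0.570476
3.13997	0.582205
3.49975	0.593533
3.90076	0.604461
4.34772	0.614994
4.84588	0.625137
5.40113	0.634898
6.02	0.644286
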