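id1	id2	P	Q	n_compared	distance	defined
sp1_ind1	sp1_ind2	0.00833333333333	0	120	0.00840355915819	True
sp1_ind1	sp1_ind3	0.00833333333333	0	120	0.00840355915819	True
sp1_ind1	sp2_ind1	0.0833333333333	0	120	0.091160778397	True
sp1_ind1	sp2_ind2	0.0916666666667	0	120	0.101262132056	True
sp1_ind1	sp2_ind3	0.0916666666667	0	120	0.101262132056	True
sp1_ind1	sp3_ind1	0.0666666666667	0.0333333333333	120	0.108408996269	True
sp1_ind1	sp3_ind2	0.075	0.0333333333333	120	0.118510349927	True
sp1_ind1	sp3_ind3	0.075	0.0333333333333	120	0.118510349927	True
sp1_ind1	sp4_ind1	0.0833333333333	0.05	120	0.14843860917	True
sp1_ind1	sp4_ind2	0.0916666666667	0.05	120	0.159191711781	True
sp1_ind1	sp4_ind3	0.0916666666667	0.05	120	0.159191711781	True
sp1_ind2	sp1_ind3	0.0166666666667	0	120	0.0169507758378	True
sp1_ind2	sp2_ind1	0.0916666666667	0	120	0.101262132056	True
sp1_ind2	sp2_ind2	0.1	0	120	0.111571775657	True
sp1_ind2	sp2_ind3	0.1	0	120	0.111571775657	True
sp1_ind2	sp3_ind1	0.075	0.0333333333333	120	0.118510349927	True
sp1_ind2	sp3_ind2	0.0833333333333	0.0333333333333	120	0.128819993529	True
sp1_ind2	sp3_ind3	0.0833333333333	0.0333333333333	120	0.128819993529	True
sp1_ind2	sp4_ind1	0.0916666666667	0.05	120	0.159191711781	True
sp1_ind2	sp4_ind2	0.1	0.05	120	0.17018116514	True
sp1_ind2	sp4_ind3	0.1	0.05	120	0.17018116514	True
sp1_ind3	sp2_ind1	0.0916666666667	0	120	0.101262132056	True
sp1_ind3	sp2_ind2	0.1	0	120	0.111571775657	True
sp1_ind3	sp2_ind3	0.1	0	120	0.111571775657	True
sp1_ind3	sp3_ind1	0.075	0.0333333333333	120	0.118510349927	True
sp1_ind3	sp3_ind2	0.0833333333333	0.0333333333333	120	0.128819993529	True
sp1_ind3	sp3_ind3	0.0833333333333	0.0333333333333	120	0.128819993529	True
sp1_ind3	sp4_ind1	0.0916666666667	0.05	120	0.159191711781	True
sp1_ind3	sp4_ind2	0.1	0.05	120	0.17018116514	True
sp1_ind3	sp4_ind3	0.1	0.05	120	0.17018116514	True
sp2_ind1	sp2_ind2	0.00833333333333	0	120	0.00840355915819	True
sp2_ind1	sp2_ind3	0.00833333333333	0	120	0.00840355915819	True
sp2_ind1	sp3_ind1	0.0833333333333	0.0333333333333	120	0.128819993529	True
sp2_ind1	sp3_ind2	0.0916666666667	0.0333333333333	120	0.139346698128	True
sp2_ind1	sp3_ind3	0.0916666666667	0.0333333333333	120	0.139346698128	True
sp2_ind1	sp4_ind1	0.1	0.05	120	0.17018116514	True
sp2_ind1	sp4_ind2	0.108333333333	0.05	120	0.181417593066	True
sp2_ind1	sp4_ind3	0.108333333333	0.05	120	0.181417593066	True
sp2_ind2	sp2_ind3	0.0166666666667	0	120	0.0169507758378	True
sp2_ind2	sp3_ind1	0.0916666666667	0.0333333333333	120	0.139346698128	True
sp2_ind2	sp3_ind2	0.1	0.0333333333333	120	0.150099800738	True
sp2_ind2	sp3_ind3	0.1	0.0333333333333	120	0.150099800738	True
sp2_ind2	sp4_ind1	0.108333333333	0.05	120	0.181417593066	True
sp2_ind2	sp4_ind2	0.116666666667	0.05	120	0.192912352179	True
sp2_ind2	sp4_ind3	0.116666666667	0.05	120	0.192912352179	True
sp2_ind3	sp3_ind1	0.0916666666667	0.0333333333333	120	0.139346698128	True
sp2_ind3	sp3_ind2	0.1	0.0333333333333	120	0.150099800738	True
sp2_ind3	sp3_ind3	0.1	0.0333333333333	120	0.150099800738	True
sp2_ind3	sp4_ind1	0.108333333333	0.05	120	0.181417593066	True
sp2_ind3	sp4_ind2	0.116666666667	0.05	120	0.192912352179	True
sp2_ind3	sp4_ind3	0.116666666667	0.05	120	0.192912352179	True
sp3_ind1	sp3_ind2	0.00833333333333	0	120	0.00840355915819	True
sp3_ind1	sp3_ind3	0.00833333333333	0	120	0.00840355915819	True
sp3_ind1	sp4_ind1	0.0833333333333	0.0833333333333	120	0.189421425424	True
sp3_ind1	sp4_ind2	0.0916666666667	0.0833333333333	120	0.20065785335	True
sp3_ind1	sp4_ind3	0.0916666666667	0.0833333333333	120	0.20065785335	True
sp3_ind2	sp3_ind3	0.0166666666667	0	120	0.0169507758378	True
sp3_ind2	sp4_ind1	0.0916666666667	0.0833333333333	120	0.20065785335	True
sp3_ind2	sp4_ind2	0.1	0.0833333333333	120	0.212152612463	True
sp3_ind2	sp4_ind3	0.1	0.0833333333333	120	0.212152612463	True
sp3_ind3	sp4_ind1	0.0916666666667	0.0833333333333	120	0.20065785335	True
sp3_ind3	sp4_ind2	0.1	0.0833333333333	120	0.212152612463	True
sp3_ind3	sp4_ind3	0.1	0.0833333333333	120	0.212152612463	True
sp4_ind1	sp4_ind2	0.00833333333333	0	120	0.00840355915819	True
sp4_ind1	sp4_ind3	0.00833333333333	0	120	0.00840355915819	True
sp4_ind2	sp4_ind3	0.0166666666667	0	120	0.0169507758378	True
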