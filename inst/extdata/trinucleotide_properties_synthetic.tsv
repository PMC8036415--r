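# Synthetic stand-in trinucleotide property table (NOT measured data).
# Five deterministic composition-based scales shaped like published
# trinucleotide property tables (bendability, nucleosome positioning,
# duplex stability in kcal/mol-like units, propeller twist in degrees-like
# units, DNase sensitivity). Replace with measured scales for real analyses.
trinucleotide	bendability	nucleosome_positioning	duplex_stability	propeller_twist	dnase_sensitivity
AAA	-0.0612	-0.0812	-5.0941	-5.5294	0.5471
AAC	-0.0908	0.0142	-6.3461	-7.1029	0.648
AAG	-0.0967	0.0083	-6.3167	-7.25	0.7
AAT	-0.0241	-0.0691	-5.1794	-5.1029	0.648
ACA	-0.0431	0.0369	-6.4843	-6.4118	0.8422
ACC	-0.1527	0.1023	-7.5363	-8.9853	0.5931
ACG	-0.1086	0.1214	-7.6569	-8.3824	0.8451
ACT	-0.0361	0.0439	-6.5196	-6.2353	0.7931
AGA	-0.0337	0.0463	-6.5314	-6.1765	0.9324
AGC	-0.1133	0.1167	-7.6333	-8.5	0.8333
AGG	-0.1492	0.1058	-7.5539	-8.8971	0.7353
AGT	-0.0467	0.0333	-6.4667	-6.5	0.8333
ATA	0.0235	-0.0465	-5.3176	-4.4118	0.8422
ATC	-0.0361	0.0439	-6.5196	-6.2353	0.7931
ATG	-0.042	0.038	-6.4902	-6.3824	0.8451
ATT	-0.0194	-0.0644	-5.2029	-4.9853	0.5931
CAA	-0.0955	0.0095	-6.3225	-7.2206	0.6363
CAC	-0.1051	0.1249	-7.6745	-8.2941	0.7873
CAG	-0.111	0.119	-7.6451	-8.4412	0.8392
CAT	-0.0384	0.0416	-6.5078	-6.2941	0.7873
CCA	-0.1575	0.0975	-7.5127	-9.1029	0.5814
CCC	-0.2671	0.1629	-8.5647	-11.6765	0.3324
CCG	-0.2229	0.1821	-8.6853	-11.0735	0.5843
CCT	-0.1504	0.1046	-7.548	-8.9265	0.5324
CGA	-0.098	0.132	-7.7098	-8.1176	0.8716
CGC	-0.1776	0.2024	-8.8118	-10.4412	0.7725
CGG	-0.2135	0.1915	-8.7324	-10.8382	0.6745
CGT	-0.111	0.119	-7.6451	-8.4412	0.7725
CTA	-0.0408	0.0392	-6.4961	-6.3529	0.7814
CTC	-0.1004	0.1296	-7.698	-8.1765	0.7324
CTG	-0.1063	0.1237	-7.6686	-8.3235	0.7843
CTT	-0.0837	0.0213	-6.3814	-6.9265	0.5324
GAA	-0.0908	0.0142	-6.3461	-7.1029	0.7147
GAC	-0.1004	0.1296	-7.698	-8.1765	0.8657
GAG	-0.1063	0.1237	-7.6686	-8.3235	0.9176
GAT	-0.0337	0.0463	-6.5314	-6.1765	0.8657
GCA	-0.1027	0.1273	-7.6863	-8.2353	0.8598
GCC	-0.2124	0.1926	-8.7382	-10.8088	0.6108
GCG	-0.1682	0.2118	-8.8588	-10.2059	0.8627
GCT	-0.0957	0.1343	-7.7216	-8.0588	0.8108
GGA	-0.1633	0.0917	-7.4833	-9.25	0.7
GGC	-0.2229	0.1821	-8.6853	-11.0735	0.651
GGG	-0.2788	0.1512	-8.5059	-11.9706	0.5029
GGT	-0.1563	0.0987	-7.5186	-9.0735	0.651
GTA	-0.0361	0.0439	-6.5196	-6.2353	0.8598
GTC	-0.0957	0.1343	-7.7216	-8.0588	0.8108
GTG	-0.1016	0.1284	-7.6922	-8.2059	0.8627
GTT	-0.079	0.026	-6.4049	-6.8088	0.6108
TAA	-0.0288	-0.0738	-5.1559	-5.2206	0.6363
TAC	-0.0384	0.0416	-6.5078	-6.2941	0.7873
TAG	-0.0443	0.0357	-6.4784	-6.4412	0.8392
TAT	0.0282	-0.0418	-5.3412	-4.2941	0.7873
TCA	-0.0408	0.0392	-6.4961	-6.3529	0.7814
TCC	-0.1504	0.1046	-7.548	-8.9265	0.5324
TCG	-0.1063	0.1237	-7.6686	-8.3235	0.7843
TCT	-0.0337	0.0463	-6.5314	-6.1765	0.7324
TGA	-0.0314	0.0486	-6.5431	-6.1176	0.8716
TGC	-0.111	0.119	-7.6451	-8.4412	0.7725
TGG	-0.1469	0.1081	-7.5657	-8.8382	0.6745
TGT	-0.0443	0.0357	-6.4784	-6.4412	0.7725
TTA	-0.0241	-0.0691	-5.1794	-5.1029	0.5814
TTC	-0.0837	0.0213	-6.3814	-6.9265	0.5324
TTG	-0.0896	0.0154	-6.352	-7.0735	0.5843
TTT	-0.0671	-0.0871	-5.0647	-5.6765	0.3324
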