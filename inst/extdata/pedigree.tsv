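sample_id	father	mother	generation
GF1	.	.	1
GM1	.	.	1
GF2	.	.	1
GM2	.	.	1
FTH	GF1	GM1	2
MTH	GF2	GM2	2
CH01	FTH	MTH	3
CH02	FTH	MTH	3
CH03	FTH	MTH	3
CH04	FTH	MTH	3
CH05	FTH	MTH	3
CH06	FTH	MTH	3
CH07	FTH	MTH	3
CH08	FTH	MTH	3
CH09	FTH	MTH	3
CH10	FTH	MTH	3
CH11	FTH	MTH	3
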