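sample	feature_index	feature
S001	45	F00045
S001	60	F00060
S001	74	F00074
S001	75	F00075
S002	2	F00002
S002	6	F00006
S002	14	F00014
S002	30	F00030
S002	39	F00039
S002	57	F00057
S003	17	F00017
S003	44	F00044
S003	45	F00045
S003	57	F00057
S003	75	F00075
S003	76	F00076
S004	26	F00026
S004	30	F00030
S004	59	F00059
S004	65	F00065
S005	7	F00007
S005	15	F00015
S005	33	F00033
S005	45	F00045
S005	49	F00049
S006	7	F00007
S006	32	F00032
S006	35	F00035
S006	38	F00038
S006	39	F00039
S006	64	F00064
S007	7	F00007
S007	16	F00016
S008	13	F00013
S008	27	F00027
S008	35	F00035
S008	44	F00044
S008	62	F00062
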