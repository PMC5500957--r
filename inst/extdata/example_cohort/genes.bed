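2	1094890	1125533	GENE0001
1	1115074	1200052	GENE0002
1	857450	941873	GENE0003
2	822942	892999	GENE0004
2	617414	657394	GENE0005
2	2588	56218	GENE0006
1	714021	784819	GENE0007
1	989040	1050477	GENE0008
1	887847	949815	GENE0009
1	548746	580033	GENE0010
2	622128	653371	GENE0011
1	644419	688590	GENE0012
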