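snp_id	chrom	pos	a1	a2	p_eve	p_gabriel	p_slli	p_dag	p_sharp_ahr	p_dag_ahr
rs4697177	4	20369187	G	T	3.0e-2	1.0e-3	1.9e-1	2.3e-2	6.7e-1	2.0e-1
rs4696975	4	20927269	A	T	1.5e-1	NA	2.0e-1	3.1e-3	3.3e-1	3.3e-1
rs6833065	4	21127809	C	T	2.9e-4	NA	2.2e-1	2.2e-1	9.1e-1	5.2e-1
rs2279674	4	21129348	G	T	5.4e-4	4.1e-1	2.3e-1	2.2e-1	9.0e-1	5.2e-1
rs1870626	4	21141706	C	G	9.3e-4	NA	2.2e-1	2.0e-1	8.9e-1	5.1e-1
rs11947661	4	21163270	A	C	1.3e-1	NA	4.6e-1	5.8e-1	2.3e-3	1.4e-1
rs402802	4	21181943	A	G	4.1e-1	1.2e-1	7.8e-1	4.4e-1	2.0e-1	2.1e-3
rs10034603	4	21339051	G	T	7.3e-4	NA	4.3e-2	NA	7.0e-1	NA
rs7378252	4	21343887	A	C	7.4e-4	NA	3.9e-2	5.3e-1	7.3e-1	6.9e-1
rs6448072	4	21352329	C	T	6.8e-3	4.6e-2	3.6e-2	5.3e-1	8.3e-1	7.1e-1
rs6856781	4	21368864	C	T	1.1e-2	4.1e-2	3.8e-2	NA	7.2e-1	NA
rs7664617	4	21471526	C	G	2.0e-2	NA	1.5e-3	3.8e-1	7.3e-1	4.1e-1
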