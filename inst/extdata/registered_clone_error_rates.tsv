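clone_id	n_genotypes	prop_complete	mismatches	error_rate	region
c1011	7	0.970	3	0.001	ES1
c1012	5	0.959	4	0.002	ES1
c1073	12	0.965	15	0.006	ES1
c1123	12	0.959	10	0.004	ES1
c1201	11	0.958	11	0.005	ES1
c2004	10	0.948	33	0.014	ES2
c2048	13	0.960	13	0.006	ES2
c2068	10	0.952	28	0.012	ES2
c3029	11	0.962	13	0.005	ES3
c3048	12	0.955	11	0.005	ES3
c3057	11	0.955	9	0.004	ES3
c3063	11	0.961	14	0.006	ES3
c6010	11	0.960	12	0.005	ES6
c6015	10	0.957	8	0.004	ES6
c6053	12	0.967	6	0.003	ES6
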