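gene_id	expected_tier	layer	probe_id	or_xy	ci_low	ci_high	q_smr	p_heidi	pp_h4
TUFM	tier1	methylation	cg00348858	0.917	0.902	0.933	1.77e-5	1	0.86
TUFM	tier1	expression	TUFM	1.029	1.025	1.034	1.08e-8	1	0.81
ISCA2	tier1	methylation	cg16374328	1.042	1.034	1.051	2.17e-5	1	0.99
ISCA2	tier1	expression	ISCA2	1.038	1.031	1.046	3.23e-6	1	0.99
HIBCH	tier1	expression	HIBCH	0.964	0.955	0.972	9.81e-4	1	0.82
HIBCH	tier1	protein	HIBCH	0.954	0.943	0.965	3.44e-4	1	0.81
COX19	tier2	methylation	cg22301154	1.053	1.040	1.066	5.25e-4	1	0.91
COX19	tier2	expression	COX19	1.056	1.036	1.076	3.00e-2	1	1.35e-17
COMT	tier2	methylation	cg19930203	1.051	1.032	1.071	4.88e-2	1	5.58e-3
COMT	tier2	protein	COMT	0.795	0.755	0.836	1.14e-4	1	0.94
GATM	tier3	methylation	cg11431346	0.926	0.902	0.951	3.21e-2	1	0.33
GATM	tier3	expression	GATM	1.025	1.018	1.033	7.98e-3	1	0.25
GATM	tier3	protein	GATM	1.083	1.059	1.109	4.29e-3	1	0.25
DCXR	tier3	methylation	cg07073120	0.933	0.913	0.953	1.71e-2	1	0.37
DCXR	tier3	expression	DCXR	1.020	1.014	1.026	1.02e-2	1	0.01
DCXR	tier3	protein	DCXR	1.223	1.169	1.280	1.49e-4	1	0.35
SPATA20	tier3	methylation	cg16020904	0.917	0.895	0.940	6.22e-3	1	4.14e-4
SPATA20	tier3	expression	SPATA20	1.017	1.013	1.021	2.58e-4	1	6.43e-4
SPATA20	tier3	protein	SPATA20	1.055	1.043	1.068	1.49e-4	1	5.27e-4
MRPL32	tier3	methylation	cg00365680	0.979	0.972	0.987	4.25e-2	1	0.11
MRPL32	tier3	expression	MRPL32	0.946	0.927	0.966	4.72e-2	1	1.17e-5
HADHA	tier3	methylation	cg08067268	0.981	0.975	0.988	2.68e-2	1	8.65e-6
HADHA	tier3	expression	HADHA	1.062	1.042	1.083	1.62e-2	1	1.05e-9
AIFM2	tier3	methylation	cg04859918	0.969	0.959	0.980	4.61e-2	1	1.04e-13
AIFM2	tier3	expression	AIFM2	0.947	0.930	0.965	2.35e-2	1	1.74e-19
SFXN5	tier3	methylation	cg03344820	0.925	0.901	0.949	2.62e-2	1	0.01
SFXN5	tier3	expression	SFXN5	1.097	1.069	1.125	3.80e-3	1	0.01
STYXL1	tier3	methylation	cg03592824	1.030	1.020	1.039	1.90e-2	1	0.22
STYXL1	tier3	expression	STYXL1	1.015	1.010	1.020	1.96e-2	1	1.74e-6
ACSM3	tier3	methylation	cg06478823	1.019	1.013	1.026	2.83e-2	1	9.39e-6
ACSM3	tier3	expression	ACSM3	0.930	0.908	0.953	2.35e-2	1	7.73e-6
SLC25A13	tier3	methylation	cg21022364	0.973	0.965	0.981	1.12e-2	1	0.32
SLC25A13	tier3	expression	SLC25A13	1.042	1.029	1.055	9.24e-3	1	0.24
MTHFS	tier3	expression	MTHFS	1.033	1.022	1.045	3.43e-2	1	2.69e-3
MTHFS	tier3	protein	MTHFS	1.030	1.019	1.041	3.25e-2	1	2.30e-3
MCL1	tier3	methylation	cg02961109	0.946	0.929	0.964	2.87e-2	1	5.75e-6
MCL1	tier3	protein	MCL1	1.085	1.064	1.105	2.13e-4	1	5.57e-9
ACADVL	tier3	methylation	cg03508063	1.066	1.046	1.087	1.16e-2	1	3.54e-3
ACADVL	tier3	protein	ACADVL	0.756	0.690	0.828	1.48e-2	1	0.01
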