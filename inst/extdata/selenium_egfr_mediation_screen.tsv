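mediator	or_xy	p_xy	or_xm	p_xm	or_my	p_my	direction	effect_class	ratio_pct
Agouti-signaling protein	0.997	0.001	0.925	0.019	1.001	0.004	TRUE	Partial	3.49
Uncharacterized protein C17orf78	0.997	0.001	1.088	0.007	0.999	0.011	TRUE	Partial	3.65
Complement C1q subcomponent subunit C	0.997	0.001	0.940	0.015	1.001	0.007	TRUE	Partial	1.59
Coiled-coil domain-containing protein 134	0.997	0.001	1.074	0.049	0.999	0.002	TRUE	Partial	3.51
Cyclin-H	0.997	0.001	1.068	0.002	0.998	<0.001	TRUE	Partial	4.44
Cilia- and flagella-associated protein 45	0.997	0.001	1.397	0.04	0.999	0.028	TRUE	Partial	15.26
Cytochrome P450 3A4	0.997	0.001	1.095	0.003	0.999	0.017	TRUE	Partial	4.19
EP300-interacting inhibitor of differentiation 3	0.997	0.001	0.907	0.002	1.001	0.02	TRUE	Partial	3.72
EMI domain-containing protein 1	0.997	0.001	1.081	0.02	0.999	0.041	TRUE	Partial	2.98
Ectonucleoside triphosphate diphosphohydrolase 3	0.997	0.001	1.085	0.012	0.999	0.049	TRUE	Partial	3.91
FAS-associated factor 2	0.997	0.001	1.213	<0.001	0.999	0.005	TRUE	Partial	9.94
Fetal and adult testis-expressed transcript protein	0.997	0.001	1.115	0.002	0.999	0.044	TRUE	Partial	3.35
Fibulin-1	0.997	0.001	0.619	0.017	1.001	0.048	TRUE	Partial	19.52
Fibroblast growth factor receptor 4	0.997	0.001	1.599	0.015	0.999	0.011	TRUE	Partial	23.70
Secreted frizzled-related protein 3	0.997	0.001	1.109	0.004	0.999	0.01	TRUE	Partial	4.48
Cell surface A33 antigen	0.997	0.001	1.161	0.001	0.999	0.01	TRUE	Partial	6.73
HEPACAM family member 2	0.997	0.001	1.118	0.013	0.999	0.017	TRUE	Partial	3.14
Hephaestin-like protein 1	0.997	0.001	1.125	0.001	0.999	0.001	TRUE	Partial	6.07
Killer cell immunoglobulin-like receptor 3DS1	0.997	0.001	1.073	0.042	0.999	0.017	TRUE	Partial	3.38
Galectin-9	0.997	0.001	1.099	0.006	0.998	0.015	TRUE	Partial	5.60
Leucine-rich repeat transmembrane neuronal protein 4	0.997	0.001	1.220	<0.001	0.999	0.024	TRUE	Partial	8.23
Matrilin-3	0.997	0.001	1.058	0.029	0.999	0.021	TRUE	Partial	2.52
Matrilin-4	0.997	0.001	0.933	0.038	1.002	<0.001	TRUE	Partial	4.50
Neuron-specific protein family member 2	0.997	0.001	1.088	0.035	0.999	0.003	TRUE	Partial	3.91
PAX-interacting protein 1	0.997	0.001	1.146	0.001	0.999	0.041	TRUE	Partial	6.28
Renin	0.997	0.001	0.930	0.018	1.001	0.01	TRUE	Partial	3.08
RING finger protein 165	0.997	0.001	0.920	0.006	1.001	0.01	TRUE	Partial	3.88
DNA-binding protein SATB1	0.997	0.001	1.100	0.016	0.999	0.032	TRUE	Partial	4.32
Sodium/iodide cotransporter	0.997	0.001	1.097	0.003	0.999	0.006	TRUE	Partial	3.48
Mothers against decapentaplegic homolog 2	0.997	0.001	0.672	0.026	1.001	0.006	TRUE	Partial	12.95
Serine protease inhibitor Kazal-type 13	0.997	0.001	1.081	<0.001	0.999	0.033	TRUE	Partial	2.88
Testis-expressed sequence 29 protein	0.997	0.001	0.946	0.023	1.001	0.001	TRUE	Partial	2.45
Torsin-1A-interacting protein 2	0.997	0.001	1.109	0.027	0.999	0.009	TRUE	Partial	4.42
Zinc finger protein 329	0.997	0.001	1.151	<0.001	0.999	0.026	TRUE	Partial	5.48
E3 ubiquitin-protein ligase ZNRF3	0.997	0.001	1.236	<0.001	0.999	0.045	TRUE	Partial	10.34
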