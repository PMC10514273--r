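taxon	av_rra_edson	av_rra_ssm	av_diss	diss_sd	contrib_pct	cum_pct
Erodium	24.99	3.98	12.00	0.98	13.39	13.39
Acmispon	2.54	17.02	8.78	0.68	9.80	23.19
Corethrogyne	5.62	13.67	8.10	0.78	9.04	32.24
Calystegia	15.01	0.79	7.54	0.66	8.41	40.65
Phacelia	1.23	10.18	5.33	0.57	5.95	46.60
Deinandra	8.07	1.76	4.43	0.46	4.95	51.55
Chorizanthe	5.06	6.90	4.42	0.78	4.93	56.48
Dichelostemma	1.04	7.03	3.74	0.47	4.18	60.66
Croton californicus	0.00	7.36	3.68	0.55	4.11	64.76
Stipa	5.03	0.95	2.69	0.60	3.01	67.77
Brassicaceae	1.10	3.94	2.20	0.65	2.46	70.23
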