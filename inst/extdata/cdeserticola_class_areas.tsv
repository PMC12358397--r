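period	nhs_high	nhs_medium	nhs_low	pcs_high	pcs_medium	pcs_low
current	26.92	47.19	64.09	23.88	46.02	62.02
ssp126_2050	31.31	42.43	59.32	26.07	40.98	56.65
ssp126_2070	31.86	43.23	57.20	29.10	41.79	58.59
ssp126_2090	37.14	41.52	58.19	37.14	37.95	56.88
ssp370_2050	35.86	43.68	61.08	30.88	40.48	58.66
ssp370_2070	52.16	45.33	60.95	40.59	42.20	63.96
ssp370_2090	53.82	42.67	62.48	48.22	41.27	62.22
ssp585_2050	40.64	41.19	57.75	33.36	41.04	57.75
ssp585_2070	49.61	42.72	63.54	40.23	44.38	60.39
ssp585_2090	52.39	45.16	63.60	48.00	43.72	60.76
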