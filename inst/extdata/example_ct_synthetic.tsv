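sample_id	group	target_ct	reference_ct	replicate
case_01	case	26.71	20.10	1
case_01	case	26.64	20.05	2
case_01	case	26.78	20.16	3
case_02	case	26.52	19.92	1
case_02	case	26.49	19.88	2
case_02	case	26.60	20.01	3
case_03	case	26.83	20.21	1
case_03	case	26.90	20.29	2
case_03	case	26.75	20.18	3
control_01	control	25.02	20.02	1
control_01	control	25.10	20.08	2
control_01	control	24.95	19.97	3
control_02	control	25.21	20.15	1
control_02	control	25.17	20.11	2
control_02	control	25.26	20.22	3
control_03	control	24.88	19.90	1
control_03	control	24.95	19.99	2
control_03	control	24.80	19.85	3
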