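participant_id	group	sex	age_band	follow_up_months	n_calls	mean_call_minutes	sd_call_minutes	mean_chars	sd_chars
C01	control	F	61-62	11	31	7.8	2.0	422.7	121.4
C02	control	F	63-64	14	32	14.0	5.1	1078.3	369.8
C03	control	F	75-77	25	75	11.3	8.5	744.8	215.5
C04	control	F	75-75	1	4	12.8	3.1	1365.0	130.6
C05	control	F	78-78	9	64	10.3	2.0	815.2	173.8
C06	control	F	79-80	6	23	11.7	3.2	1507.5	457.4
C07	control	F	80-83	33	109	16.6	4.7	1499.7	391.7
C08	control	F	82-83	19	72	6.8	3.0	811.2	367.9
C09	control	F	88-89	17	104	11.2	4.4	944.5	314.2
C10	control	F	91-91	9	35	22.2	3.7	2405.8	433.2
C11	control	M	63-65	16	72	11.9	3.1	1146.8	242.9
C12	control	M	67-70	33	132	10.6	2.3	999.4	236.5
C13	control	M	82-85	30	226	17.7	6.3	1207.0	497.7
A01	AD	F	83-84	14	40	9.5	2.8	923.9	409.2
A02	AD	F	85-85	5	13	7.8	1.8	662.0	199.1
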