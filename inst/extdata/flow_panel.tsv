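sample_id	predicted_ploidy	genome_size_pg	lineage
A10	4	2.01	EU
A2	4	1.98	EU
A3	4	1.89	EU
A5	8	3.95	EU
A7	8	3.91	EU
A8	6	NA	EU
A9	4	NA	Med
B2	6	NA	EU
C10	4	2.05	EU
C11	4	2.07	EU
C12	4	2.16	EU
C13	4	2.10	EU
C2	8	4.11	AU
C3	8	3.91	AU
C6	8	4.03	AU
C7	8	4.02	AU
C9	4	1.98	EU
D11	4	2.03	EU
D12	4	1.98	EU
D13	4	2.00	EU
D4	4	2.02	EU
D5	4	NA	Med
D6	4	NA	EU
D7	4	1.98	EU
D9	4	NA	EU
E12	4	2.25	USnat
E13	4	1.95	Med
E3	4	NA	EU
E9	4	1.90	Med
F13	4	NA	EU
F2	8	3.89	admix
F9	4	NA	Med
H1	8	4.00	AU
H2	6	NA	admix
H5	4	1.90	Med
H6	4	2.09	EU
I12	4	3.92	Med
K12	4	NA	admix
K13	8	4.06	admix
K2	6	2.97	EU
Y1	8	4.04	AU
Y10	4	1.94	EU
Y11	4	1.94	EU
Y12	6	3.09	USland
Y13	4	1.96	EU
Y14	4	2.00	EU
Y15	4	1.99	EU
Y16	4	2.04	EU
Y17	4	2.03	USnat
Y18	4	1.92	Med
Y19	4	1.96	EU
Y20	4	1.96	EU
Y21	4	NA	Med
Y22	4	1.97	EU
Y23	4	1.92	EU
Y24	4	NA	EU
Y25	8	4.00	AU
Y26	4	2.07	Med
Y27	4	2.25	USnat
Y28	4	1.97	Med
Y3	8	3.95	admix
Y30	6	3.12	USland
Y31	4	1.92	EU
Y32	4	NA	CN
Y33	6	NA	USland
Y34	4	2.02	Med
Y35	6	3.09	USland
Y36	8	3.93	admix
Y37	6	NA	USland
Y38	4	NA	CN
Y39	8	NA	AU
Y4	4	2.02	EU
Y40	4	NA	CN
Y41	4	NA	CN
Y43	8	NA	admix
Y44	6	NA	admix
Y45	4	NA	CN
Y46	4	NA	CN
Y47	4	NA	CN
Y48	8	NA	admix
Y49	8	NA	admix
Y51	8	NA	AU
Y53	8	NA	AU
Y55	4	NA	admix
Y57	4	NA	CN
Y6	8	4.05	AU
Y7	6	3.17	USland
Y9	8	NA	AU
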