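taxon_id	community_1	community_2	community_3	community_4	community_5	community_6	community_7	community_8	community_9	community_10	community_11	community_12	community_13	community_14	community_15	community_16	community_17	community_18	community_19	community_20	taxonomy
taxon_1	36	29	104	91	42	38	65	62	30	108	77	71	48	25	77	76	35	68	60	36	Bacteria;PhylumA;ClassX;OrderY;FamilyZ;Genus01
taxon_2	6	2	25	27	28	8	7	25	10	15	8	8	14	14	24	51	6	12	35	13	Bacteria;PhylumA;ClassX;OrderY;FamilyZ;Genus02
taxon_3	36	42	43	36	27	48	40	47	35	36	25	32	28	54	25	40	63	21	43	21	Bacteria;PhylumA;ClassX;OrderY;FamilyZ;Genus03
taxon_4	1	40	0	5	18	0	4	0	8	0	2	0	1	0	0	2	7	4	18	2	Bacteria;PhylumA;ClassX;OrderY;FamilyZ;Genus04
taxon_5	32	33	41	42	34	18	19	16	45	14	5	3	20	30	7	9	20	10	30	61	Bacteria;PhylumA;ClassX;OrderY;FamilyZ;Genus05
taxon_6	10	8	36	24	9	3	4	7	3	0	6	8	0	2	7	6	3	4	3	0	Bacteria;PhylumA;ClassX;OrderY;FamilyZ;Genus06
taxon_7	33	45	24	8	11	11	27	21	46	45	37	11	47	62	19	17	41	22	25	79	Bacteria;PhylumA;ClassX;OrderY;FamilyZ;Genus07
taxon_8	27	51	31	10	21	41	40	89	18	23	39	18	22	55	31	98	9	25	36	19	Bacteria;PhylumA;ClassX;OrderY;FamilyZ;Genus08
taxon_9	3	0	1	15	4	35	11	15	25	11	3	4	6	5	11	4	51	9	4	28	Bacteria;PhylumA;ClassX;OrderY;FamilyZ;Genus09
taxon_10	0	0	0	0	0	0	0	0	0	12	0	0	0	0	2	0	0	0	0	0	Bacteria;PhylumA;ClassX;OrderY;FamilyZ;Genus10
taxon_11	5	8	16	21	31	14	21	18	12	26	33	23	32	35	15	4	47	14	24	11	Bacteria;PhylumB;ClassX;OrderY;FamilyZ;Genus11
taxon_12	16	58	52	11	11	13	28	29	33	7	6	28	5	39	17	50	9	30	28	16	Bacteria;PhylumB;ClassX;OrderY;FamilyZ;Genus12
taxon_13	1	6	0	0	37	8	3	1	0	1	3	0	0	8	3	10	12	28	47	1	Bacteria;PhylumB;ClassX;OrderY;FamilyZ;Genus13
taxon_14	8	7	23	5	14	4	13	13	10	33	31	14	1	4	8	11	19	20	12	8	Bacteria;PhylumB;ClassX;OrderY;FamilyZ;Genus14
taxon_15	32	52	12	58	22	39	17	29	3	16	23	14	81	17	20	2	16	42	20	8	Bacteria;PhylumB;ClassX;OrderY;FamilyZ;Genus15
taxon_16	29	22	48	13	54	26	38	38	41	28	22	38	26	11	11	54	19	19	29	26	Bacteria;PhylumB;ClassX;OrderY;FamilyZ;Genus16
taxon_17	5	3	0	5	5	13	0	4	5	1	2	4	7	6	4	0	16	12	1	12	Bacteria;PhylumB;ClassX;OrderY;FamilyZ;Genus17
taxon_18	4	4	2	1	0	2	11	0	16	5	0	0	4	5	55	0	2	18	2	4	Bacteria;PhylumB;ClassX;OrderY;FamilyZ;Genus18
taxon_19	13	13	3	4	0	23	6	3	22	14	7	8	2	16	6	0	7	10	6	2	Bacteria;PhylumB;ClassX;OrderY;FamilyZ;Genus19
taxon_20	7	45	10	33	31	8	19	5	22	4	11	23	2	20	19	5	14	6	9	9	Bacteria;PhylumB;ClassX;OrderY;FamilyZ;Genus20
taxon_21	14	7	12	2	3	1	0	16	5	1	23	31	4	0	3	2	0	6	8	0	Bacteria;PhylumC;ClassX;OrderY;FamilyZ;Genus21
taxon_22	3	3	0	4	1	1	3	3	1	2	0	5	2	8	6	7	17	0	13	0	Bacteria;PhylumC;ClassX;OrderY;FamilyZ;Genus22
taxon_23	0	4	3	3	0	0	2	15	0	18	0	1	0	10	0	1	0	7	0	0	Bacteria;PhylumC;ClassX;OrderY;FamilyZ;Genus23
taxon_24	2	9	1	5	1	3	0	20	11	0	18	9	13	0	7	25	5	7	15	8	Bacteria;PhylumC;ClassX;OrderY;FamilyZ;Genus24
taxon_25	3	21	2	0	73	6	16	12	18	7	12	9	24	7	7	2	7	9	0	0	Bacteria;PhylumC;ClassX;OrderY;FamilyZ;Genus25
taxon_26	1	6	0	3	2	4	23	7	0	3	14	4	2	9	11	31	22	0	2	3	Bacteria;PhylumC;ClassX;OrderY;FamilyZ;Genus26
taxon_27	50	6	21	15	34	17	24	31	13	31	51	26	16	11	13	21	33	70	11	13	Bacteria;PhylumC;ClassX;OrderY;FamilyZ;Genus27
taxon_28	4	0	0	0	2	14	0	11	0	0	1	0	1	0	0	2	1	0	4	0	Bacteria;PhylumC;ClassX;OrderY;FamilyZ;Genus28
taxon_29	3	10	11	46	4	28	7	4	0	5	7	31	3	12	3	8	3	0	0	6	Bacteria;PhylumC;ClassX;OrderY;FamilyZ;Genus29
taxon_30	32	7	10	13	4	1	1	9	6	2	4	7	2	5	2	3	9	1	7	4	Bacteria;PhylumC;ClassX;OrderY;FamilyZ;Genus30
taxon_31	1	1	0	0	0	7	0	0	11	0	0	0	0	0	0	0	1	0	0	0	Bacteria;PhylumD;ClassX;OrderY;FamilyZ;Genus31
taxon_32	12	9	2	0	4	5	4	0	9	2	3	1	4	10	3	3	31	1	9	18	Bacteria;PhylumD;ClassX;OrderY;FamilyZ;Genus32
taxon_33	30	21	10	18	1	37	31	23	41	5	19	21	3	24	33	32	15	11	8	26	Bacteria;PhylumD;ClassX;OrderY;FamilyZ;Genus33
taxon_34	36	0	1	0	0	2	5	0	31	2	14	0	0	7	2	9	10	3	3	30	Bacteria;PhylumD;ClassX;OrderY;FamilyZ;Genus34
taxon_35	0	10	0	2	3	2	21	1	9	15	9	12	1	6	9	7	0	2	1	0	Bacteria;PhylumD;ClassX;OrderY;FamilyZ;Genus35
taxon_36	28	27	34	25	31	19	66	39	58	34	62	108	4	60	34	15	35	46	12	39	Bacteria;PhylumD;ClassX;OrderY;FamilyZ;Genus36
taxon_37	14	14	25	12	7	35	19	8	14	7	16	28	23	4	22	2	7	36	37	27	Bacteria;PhylumD;ClassX;OrderY;FamilyZ;Genus37
taxon_38	10	8	12	4	38	1	9	28	9	1	0	7	11	24	3	17	7	14	26	12	Bacteria;PhylumD;ClassX;OrderY;FamilyZ;Genus38
taxon_39	35	22	54	44	11	34	15	36	9	30	55	24	65	33	24	66	29	5	52	38	Bacteria;PhylumD;ClassX;OrderY;FamilyZ;Genus39
taxon_40	32	34	10	17	2	16	7	28	4	19	16	37	35	34	10	13	15	19	24	17	Bacteria;PhylumD;ClassX;OrderY;FamilyZ;Genus40
taxon_41	3	13	13	19	24	17	6	4	5	28	26	8	37	11	47	27	10	5	16	37	Bacteria;PhylumE;ClassX;OrderY;FamilyZ;Genus41
taxon_42	0	3	2	8	12	11	12	3	1	5	0	0	0	0	61	9	14	10	3	3	Bacteria;PhylumE;ClassX;OrderY;FamilyZ;Genus42
taxon_43	42	1	11	26	4	5	8	4	6	42	12	13	42	8	10	11	22	8	9	3	Bacteria;PhylumE;ClassX;OrderY;FamilyZ;Genus43
taxon_44	10	30	16	39	6	27	4	9	15	17	8	40	18	0	11	12	6	2	11	13	Bacteria;PhylumE;ClassX;OrderY;FamilyZ;Genus44
taxon_45	1	10	21	28	23	6	25	3	9	28	4	19	5	18	5	2	20	5	3	19	Bacteria;PhylumE;ClassX;OrderY;FamilyZ;Genus45
taxon_46	22	2	39	30	30	13	18	27	30	22	13	19	24	39	6	3	7	36	25	24	Bacteria;PhylumE;ClassX;OrderY;FamilyZ;Genus46
taxon_47	8	4	10	23	13	10	3	17	59	23	4	9	9	14	14	3	7	17	23	6	Bacteria;PhylumE;ClassX;OrderY;FamilyZ;Genus47
taxon_48	12	20	12	11	31	60	11	13	3	18	12	24	27	24	12	19	64	20	26	16	Bacteria;PhylumE;ClassX;OrderY;FamilyZ;Genus48
taxon_49	48	17	32	39	34	39	51	15	30	25	43	29	30	30	44	46	23	21	25	112	Bacteria;PhylumE;ClassX;OrderY;FamilyZ;Genus49
taxon_50	13	32	3	11	7	24	2	16	19	15	2	2	28	0	14	4	36	21	17	31	Bacteria;PhylumE;ClassX;OrderY;FamilyZ;Genus50
taxon_51	22	20	8	10	10	4	16	40	6	13	7	2	37	13	4	15	13	4	14	8	Bacteria;PhylumF;ClassX;OrderY;FamilyZ;Genus51
taxon_52	0	0	0	0	0	5	0	3	0	0	1	0	0	0	0	0	0	0	0	0	Bacteria;PhylumF;ClassX;OrderY;FamilyZ;Genus52
taxon_53	26	8	9	15	9	5	16	3	3	3	8	16	10	11	4	12	5	33	9	4	Bacteria;PhylumF;ClassX;OrderY;FamilyZ;Genus53
taxon_54	18	18	49	7	25	19	87	15	35	75	46	40	40	28	33	38	24	66	17	21	Bacteria;PhylumF;ClassX;OrderY;FamilyZ;Genus54
taxon_55	77	26	42	24	47	33	46	31	23	41	26	24	56	58	42	29	25	21	73	37	Bacteria;PhylumF;ClassX;OrderY;FamilyZ;Genus55
taxon_56	34	43	16	14	37	46	11	26	62	21	51	12	39	29	69	33	11	50	22	23	Bacteria;PhylumF;ClassX;OrderY;FamilyZ;Genus56
taxon_57	0	0	0	0	8	0	18	0	0	0	2	22	0	1	0	14	0	0	0	1	Bacteria;PhylumF;ClassX;OrderY;FamilyZ;Genus57
taxon_58	3	2	9	39	5	31	1	0	4	5	7	2	1	8	0	1	3	19	0	0	Bacteria;PhylumF;ClassX;OrderY;FamilyZ;Genus58
taxon_59	27	56	16	16	29	38	21	48	13	3	52	26	6	5	43	9	34	23	35	36	Bacteria;PhylumF;ClassX;OrderY;FamilyZ;Genus59
taxon_60	20	8	13	19	26	22	18	10	44	33	12	25	32	31	28	8	33	28	8	9	Bacteria;PhylumF;ClassX;OrderY;FamilyZ;Genus60
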