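gene_id	chromosome	start	stop	strand	n_exons	intron_position	type_edstam	type_boutrot	full_length	signal_length	mature_length	ecm_length	ecm_descriptor
Solyc01g081600.2.1	1	80791839	80793152	-	2	5	1	I	121	29	92	85	C-X9-C-X14-CC-X19-CXC-X21-C-X13-C
Solyc01g090350.2.1	1	84055544	84056304	-	2	5	1	I	120	21	99	85	C-X9-C-X13-CC-X19-CXC-X22-C-X13-C
Solyc01g090360.2.1	1	84060227	84061028	-	2	5	1	I	115	23	92	85	C-X9-C-X13-CC-X19-CXC-X22-C-X13-C
Solyc01g095780.2.1	1	86968123	86968735	-	1		1	I	112	21	91	88	C-X9-C-X16-CC-X19-CXC-X21-C-X14-C
Solyc02g087910.1.1	2	50167356	50167715	+	1		1	I	119	21	98	85	C-X9-C-X13-CC-X19-CXC-X22-C-X13-C
Solyc06g005770.1.1	6	808170	808529	+	1		1	I	119	27	92	85	C-X9-C-X13-CC-X19-CXC-X22-C-X13-C
Solyc06g005780.1.1	6	812314	812670	+	1		1	I	118	23	95	85	C-X9-C-X13-CC-X19-CXC-X22-C-X13-C
Solyc06g065600.1.1	6	40981932	40982291	+	1		1	I	119	27	92	85	C-X9-C-X13-CC-X19-CXC-X22-C-X13-C
Solyc08g067500.1.1	8	56511766	56512137	+	1		1	I	123	27	96	89	C-X9-C-X16-CC-X19-CXC-X23-C-X13-C
Solyc08g067510.1.1	8	56518886	56519254	+	1		1	I	122	29	93	86	C-X9-C-X13-CC-X19-CXC-X22-C-X14-C
Solyc08g067520.1.1	8	56545559	56545927	+	1		1	I	122	24	98	86	C-X9-C-X14-CC-X19-CXC-X22-C-X13-C
Solyc08g067530.1.1	8	56548525	56548878	+	1		1	I	117	24	93	86	C-X9-C-X14-CC-X19-CXC-X22-C-X13-C
Solyc08g067540.1.1	8	56552776	56553138	+	1		1	I	120	24	96	86	C-X9-C-X14-CC-X19-CXC-X22-C-X13-C
Solyc08g067550.1.1	8	56562356	56562742	+	1		1	I	128	25	103	86	C-X9-C-X14-CC-X19-CXC-X22-C-X13-C
Solyc09g008500.1.1	9	1984459	1985345	-	2	5	1	I	113	22	91	84	C-X9-C-X12-CC-X19-CXC-X22-C-X13-C
Solyc09g018010.2.1	9	12593647	12594913	+	3	5	1	I	110	20	90	84	C-X9-C-X12-CC-X19-CXC-X22-C-X13-C
Solyc10g075050.1.1	10	58748414	58749215	-	2	5	1	I	116	26	90	84	C-X9-C-X12-CC-X19-CXC-X22-C-X13-C
Solyc10g075060.1.1	10	58756396	58756930	-	2	5	1	I	114	24	90	84	C-X9-C-X12-CC-X19-CXC-X22-C-X13-C
Solyc10g075070.1.1	10	58785125	58785597	-	2	5	1	I	114	24	90	84	C-X9-C-X12-CC-X19-CXC-X22-C-X13-C
Solyc10g075090.1.1	10	58800507	58801024	-	2	10	1	I	121	24	97	84	C-X9-C-X12-CC-X19-CXC-X22-C-X13-C
Solyc10g075100.1.1	10	58810582	58811212	-	2	5	1	I	114	24	90	84	C-X9-C-X12-CC-X19-CXC-X22-C-X13-C
Solyc10g075110.1.1	10	58832488	58833096	-	2	5	1	I	114	24	90	84	C-X9-C-X12-CC-X19-CXC-X22-C-X13-C
Solyc10g075150.1.1	10	58873651	58874859	-	2	5	1	I	113	23	90	84	C-X9-C-X12-CC-X19-CXC-X22-C-X13-C
Solyc10g076200.1.1	10	59051770	59052216	+	2	5	1	I	113	22	91	84	C-X9-C-X12-CC-X19-CXC-X22-C-X13-C
Solyc02g086310.1.1	2	49003403	49003687	-	1		2	II	94	26	68	66	C-X7-C-X13-CC-X8-CXC-X23-C-X6-C
Solyc03g034330.1.1	3	6121300	6121593	-	1		2	II	97	28	69	67	C-X7-C-X14-CC-X8-CXC-X23-C-X6-C
Solyc03g034380.1.1	3	6240690	6240992	-	1		2	II	100	27	73	70	C-X7-C-X17-CC-X8-CXC-X23-C-X6-C
Solyc03g034390.1.1	3	6247676	6247963	-	1		2	II	95	25	70	67	C-X8-C-X13-CC-X8-CXC-X23-C-X6-C
Solyc03g119210.1.1	3	67871587	67871868	+	1		2	II	93	25	68	66	C-X7-C-X13-CC-X8-CXC-X23-C-X6-C
Solyc06g069070.1.1	6	42868895	42869179	+	1		2	II	94	26	68	66	C-X7-C-X13-CC-X8-CXC-X23-C-X6-C
Solyc01g009590.2.1	1	3831235	3832490	-	2	4	C	III	102	35	67	59	C-X9-C-X14-CC-X9-CXC-X12-C-X6-C
Solyc06g035820.1.1	6	25056565	25056864	+	1		C	III	99	28	71	61	C-X9-C-X16-CC-X9-CXC-X12-C-X6-C
Solyc01g066910.2.1	1	75179261	75179854	+	1		n.d.	IV	101	25	76	73	C-X9-C-X15-CC-X9-CXC-X24-C-X7-C
Solyc01g109390.2.1	1	96361928	96362671	+	1		n.d.	IV	104	27	77	72	C-X9-C-X15-CC-X9-CXC-X24-C-X6-C
Solyc03g121900.1.1	3	69923546	69923866	-	1		n.d.	IV	106	30	76	73	C-X9-C-X15-CC-X9-CXC-X24-C-X7-C
Solyc01g081590.2.1	1	80790002	80791273	-	2	4	n.d.	X	120	26	94	88	C-X9-C-X17-CC-X19-CXC-X21-C-X13-C
Solyc06g059790.2.1	6	37689909	37690759	+	3	5	n.d.	X	118	26	92	86	C-X9-C-X14-CC-X21-CXC-X20-C-X13-C
Solyc06g059830.1.1	6	37724798	37725157	-	1		n.d.	X	119	27	92	87	C-X10-C-X14-CC-X21-CXC-X21-C-X12-C
Solyc10g012110.1.1	10	4440329	4440950	-	2	5	n.d.	X	114	20	94	87	C-X10-C-X14-CC-X20-CXC-X21-C-X13-C
Solyc10g012120.1.1	10	4447091	4447429	-	1		n.d.	X	112	20	92	87	C-X10-C-X14-CC-X20-CXC-X21-C-X13-C
Solyc10g012130.1.1	10	4472975	4473310	-	1		n.d.	X	111	20	91	87	C-X10-C-X14-CC-X20-CXC-X21-C-X13-C
Solyc01g090970.2.1	1	84676405	84677350	-	1		D	XI	122	23	99	83	C-X9-C-X18-CC-X13-CXC-X25-C-X9-C
Solyc03g083990.1.1	3	53931600	53931971	-	1		D	XI	123	28	95	82	C-X9-C-X18-CC-X13-CXC-X24-C-X9-C
Solyc03g090990.1.1	3	54102918	54103247	+	1		n.d.	XI	109	25	84	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc03g091000.1.1	3	54111309	54111638	+	1		n.d.	XI	109	25	84	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc03g091010.1.1	3	54121867	54122196	+	1		n.d.	XI	109	25	84	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc03g091020.1.1	3	54145663	54145992	+	1		n.d.	XI	109	25	84	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc03g091030.1.1	3	54168770	54169099	+	1		n.d.	XI	109	25	84	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc03g091040.1.1	3	54190208	54190538	+	1		n.d.	XI	109	25	84	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc03g093050.1.1	3	54215797	54216126	+	1		n.d.	XI	109	25	84	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc03g093060.1.1	3	54224072	54224401	+	1		n.d.	XI	109	25	84	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc03g093070.1.1	3	54228131	54228484	+	1		n.d.	XI	117	25	92	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc06g060640.1.1	6	38662488	38662892	-	1		n.d.	XI	134	27	107	86	C-X9-C-X22-CC-X13-CXC-X24-C-X9-C
Solyc06g065970.1.1	6	41353384	41353764	+	1		D	XI	126	22	104	83	C-X9-C-X18-CC-X13-CXC-X25-C-X9-C
Solyc08g005960.1.1	8	725778	726188	-	1		D	XI	136	26	110	82	C-X9-C-X18-CC-X13-CXC-X24-C-X9-C
Solyc08g074480.1.1	8	58582336	58582731	+	1		D	XI	131	24	107	82	C-X9-C-X18-CC-X13-CXC-X24-C-X9-C
Solyc08g078900.1.1	8	62575865	62576281	-	1		n.d.	XI	138	25	113	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc08g078910.1.1	8	62579392	62579787	-	1		n.d.	XI	131	22	109	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc08g078930.1.1	8	62585978	62586385	-	1		n.d.	XI	135	21	114	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc08g078940.1.1	8	62591521	62591934	+	1		n.d.	XI	137	24	113	83	C-X9-C-X19-CC-X13-CXC-X24-C-X9-C
Solyc08g079190.1.1	8	62820130	62820546	-	1		n.d.	XI	138	25	113	84	C-X9-C-X20-CC-X13-CXC-X24-C-X9-C
Solyc08g079200.1.1	8	62823262	62823669	-	1		n.d.	XI	135	25	110	84	C-X9-C-X20-CC-X13-CXC-X24-C-X9-C
Solyc08g079230.1.1	8	62845902	62846318	+	1		n.d.	XI	138	25	113	84	C-X9-C-X20-CC-X13-CXC-X24-C-X9-C
Solyc12g014620.1.1	12	5627530	5627901	-	1		D	XI	123	25	98	82	C-X9-C-X18-CC-X13-CXC-X24-C-X9-C
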