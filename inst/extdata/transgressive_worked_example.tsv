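contig_id	A_full	H_full	P_full	A_red	H_red	P_red	printed_direction
BigSet000391	29	4	36	13	4	36	LOW
BigSet003246	44	4	28	68	4	28	LOW
BigSet010982	1	47	1	0	52	1	HIGH
BigSet009445	4	50	0	8	6	0	HIGH
BigSet011026	1	15	0	1	12	0	HIGH
BigSet015125	11	89	10	20	48	10	HIGH
BigSet011931	0	69	4	0	50	4	HIGH
BigSet009443	4	27	2	7	31	2	HIGH
BigSet007352	5	122	7	3	139	7	HIGH
BigSet015238	0	10	0	0	11	0	HIGH
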