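chrT	0	1000	chrT	5000	6000	L01	3	3
chrT	2500000	2501000	chrT	2505000	2506000	L02	3	2.999
chrT	5000000	5001000	chrT	5004999	5005999	L03	3	3
chrT	7500000	7501000	chrT	7504999	7505999	L04	3	2.9
chrT	10000000	10001000	chrT	10050000	10051000	L05	3	2.9
chrT	12500000	12501000	chrT	12600000	12601000	L06	3	3
chrT	15000000	15001000	chrT	15005001	15006001	L07	3	3.001
chrT	17500000	17501000	chrT	17506000	17507000	L08	10	10
chrT	20000000	20001000	chrT	20010000	20011000	L09	2	2
chrT	22500000	22501000	chrT	22504000	22505000	L10	50	50
chrT	25000000	25001000	chrT	27000000	27001000	L11	3	3
chrT	27500000	27501000	chrT	27505000	27506000	L12	1000	1000
chrT	30000000	30001000	chrT	30007500	30008500	L13	3	2.9999
chrT	32500000	32501000	chrT	32507500	32508500	L14	3	3.0001
chrT	35000000	35001000	chrT	35005500	35006500	L15	4	3.5
chrT	37500000	37501000	chrT	37504500	37505500	L16	4	3.5
chrT	40000000	40001000	chrT	40009999	40010999	L17	1	1
chrT	42500000	42501000	chrT	42623456	42624456	L18	4	4.2
chrT	45000000	45001000	chrT	45005000	45006000	L19	2	2
chrT	47500000	47501000	chrT	47588888	47589888	L20	3	3
chrT	50000000	50001000	chrT	50012000	50013000	L21	2	2.5
chrT	52500000	52501000	chrT	52513000	52514000	L22	3	3.1
chrT	55000000	55001000	chrT	55004998	55005998	L23	100	100
chrT	57500000	57501000	chrT	57505002	57506002	L24	3	3
chrT	60000000	60001000	chrT	60600000	60601000	L25	3	2.99
chrT	62500000	62501000	chrT	63200000	63201000	L26	3	3.01
chrT	65000000	65001000	chrT	65005000	65006000	L27	5	5
chrT	67500000	67501000	chrT	67504999	67505999	L28	5	4.999
chrT	70000000	70001000	chrT	70030000	70031000	L29	3	3
chrT	72500000	72501000	chrT	72515000	72516000	L30	1	0.5
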