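region	family	n_species	n_endemic
CAB	Modulidae	2	1
CAB	Conidae	55	52
CAB	Muricinae	2	1
CAB	Olivinae	1	1
WAF	Modulidae	1	0
WAF	Conidae	15	8
WAF	Muricinae	8	1
WAF	Olivinae	1	0
WAF	Plesiotritoninae	1	0
MAD	Conidae	1	0
MAD	Muricinae	1	0
CAN	Modulidae	1	0
CAN	Conidae	5	0
CAN	Muricinae	4	0
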