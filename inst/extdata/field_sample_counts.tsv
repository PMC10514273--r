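year	season	site	grid	count
2016	fall	EDSON	663	6
2016	fall	EDSON	819	6
2016	fall	SSM	1433	0
2016	fall	SSM	1450	0
2016	fall	SSM	1452	0
2016	spring	EDSON	663	15
2016	spring	EDSON	819	10
2016	spring	SSM	1433	10
2016	spring	SSM	1450	9
2016	spring	SSM	1452	11
2016	summer	EDSON	663	12
2016	summer	EDSON	819	7
2016	summer	SSM	1433	6
2016	summer	SSM	1450	12
2016	summer	SSM	1452	3
2017	fall	EDSON	663	7
2017	fall	EDSON	819	10
2017	fall	SSM	1433	9
2017	fall	SSM	1450	1
2017	fall	SSM	1452	4
2017	spring	EDSON	663	3
2017	spring	EDSON	819	1
2017	spring	SSM	1433	16
2017	spring	SSM	1450	13
2017	spring	SSM	1452	12
2017	summer	EDSON	663	2
2017	summer	EDSON	819	9
2017	summer	SSM	1433	9
2017	summer	SSM	1450	10
2017	summer	SSM	1452	8
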