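term	gene
GO:DEMO1 lipid metabolic process	g001
GO:DEMO1 lipid metabolic process	g002
GO:DEMO1 lipid metabolic process	g003
GO:DEMO1 lipid metabolic process	g004
GO:DEMO1 lipid metabolic process	g005
GO:DEMO1 lipid metabolic process	g006
GO:DEMO1 lipid metabolic process	g007
GO:DEMO1 lipid metabolic process	g008
GO:DEMO1 lipid metabolic process	g009
GO:DEMO1 lipid metabolic process	g010
GO:DEMO1 lipid metabolic process	g011
GO:DEMO1 lipid metabolic process	g012
GO:DEMO1 lipid metabolic process	g013
GO:DEMO1 lipid metabolic process	g014
GO:DEMO1 lipid metabolic process	g015
GO:DEMO1 lipid metabolic process	g016
GO:DEMO1 lipid metabolic process	g017
GO:DEMO1 lipid metabolic process	g018
GO:DEMO1 lipid metabolic process	g019
GO:DEMO1 lipid metabolic process	g020
GO:DEMO2 transport	g030
GO:DEMO2 transport	g031
GO:DEMO2 transport	g032
GO:DEMO2 transport	g033
GO:DEMO2 transport	g034
GO:DEMO2 transport	g035
GO:DEMO2 transport	g036
GO:DEMO2 transport	g037
GO:DEMO2 transport	g038
GO:DEMO2 transport	g039
GO:DEMO2 transport	g040
GO:DEMO2 transport	g041
GO:DEMO2 transport	g042
GO:DEMO2 transport	g043
GO:DEMO2 transport	g044
GO:DEMO2 transport	g070
GO:DEMO2 transport	g071
GO:DEMO2 transport	g072
GO:DEMO2 transport	g073
GO:DEMO2 transport	g074
GO:DEMO2 transport	g075
GO:DEMO2 transport	g076
GO:DEMO2 transport	g077
GO:DEMO2 transport	g078
GO:DEMO2 transport	g079
GO:DEMO2 transport	g080
GO:DEMO2 transport	g081
GO:DEMO2 transport	g082
GO:DEMO2 transport	g083
GO:DEMO2 transport	g084
GO:DEMO3 housekeeping	g060
GO:DEMO3 housekeeping	g061
GO:DEMO3 housekeeping	g062
GO:DEMO3 housekeeping	g063
GO:DEMO3 housekeeping	g064
GO:DEMO3 housekeeping	g065
GO:DEMO3 housekeeping	g066
GO:DEMO3 housekeeping	g067
GO:DEMO3 housekeeping	g068
GO:DEMO3 housekeeping	g069
GO:DEMO3 housekeeping	g070
GO:DEMO3 housekeeping	g071
GO:DEMO3 housekeeping	g072
GO:DEMO3 housekeeping	g073
GO:DEMO3 housekeeping	g074
GO:DEMO3 housekeeping	g075
GO:DEMO3 housekeeping	g076
GO:DEMO3 housekeeping	g077
GO:DEMO3 housekeeping	g078
GO:DEMO3 housekeeping	g079
GO:DEMO3 housekeeping	g080
GO:DEMO3 housekeeping	g081
GO:DEMO3 housekeeping	g082
GO:DEMO3 housekeeping	g083
GO:DEMO3 housekeeping	g084
GO:DEMO3 housekeeping	g085
GO:DEMO3 housekeeping	g086
GO:DEMO3 housekeeping	g087
GO:DEMO3 housekeeping	g088
GO:DEMO3 housekeeping	g089
GO:DEMO3 housekeeping	g090
GO:DEMO3 housekeeping	g091
GO:DEMO3 housekeeping	g092
GO:DEMO3 housekeeping	g093
GO:DEMO3 housekeeping	g094
GO:DEMO3 housekeeping	g095
GO:DEMO3 housekeeping	g096
GO:DEMO3 housekeeping	g097
GO:DEMO3 housekeeping	g098
GO:DEMO3 housekeeping	g099
GO:DEMO3 housekeeping	g100
GO:DEMO3 housekeeping	g101
GO:DEMO3 housekeeping	g102
GO:DEMO3 housekeeping	g103
GO:DEMO3 housekeeping	g104
GO:DEMO3 housekeeping	g105
GO:DEMO3 housekeeping	g106
GO:DEMO3 housekeeping	g107
GO:DEMO3 housekeeping	g108
GO:DEMO3 housekeeping	g109
GO:DEMO3 housekeeping	g110
GO:DEMO3 housekeeping	g111
GO:DEMO3 housekeeping	g112
GO:DEMO3 housekeeping	g113
GO:DEMO3 housekeeping	g114
GO:DEMO3 housekeeping	g115
GO:DEMO3 housekeeping	g116
GO:DEMO3 housekeeping	g117
GO:DEMO3 housekeeping	g118
GO:DEMO3 housekeeping	g119
GO:DEMO3 housekeeping	g120
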