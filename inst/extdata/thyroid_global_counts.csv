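measure,sex,year,count
prevalence,both,1990,772090
incidence,both,1990,95026
deaths,both,1990,22065
dalys,both,1990,648235
ylls,both,1990,599107
ylds,both,1990,49129
prevalence,female,1990,585224
incidence,female,1990,70852
deaths,female,1990,14509
dalys,female,1990,421306
ylls,female,1990,385301
ylds,female,1990,36005
prevalence,male,1990,186866
incidence,male,1990,24174
deaths,male,1990,7557
dalys,male,1990,226929
ylls,male,1990,213806
ylds,male,1990,13124
prevalence,both,2017,2144939
incidence,both,2017,255489
deaths,both,2017,41235
dalys,both,2017,1133175
ylls,both,2017,1001180
ylds,both,2017,131995
prevalence,female,2017,1530875
incidence,female,2017,179401
deaths,female,2017,24076
dalys,female,2017,664929
ylls,female,2017,573957
ylds,female,2017,90972
prevalence,male,2017,614063
incidence,male,2017,76088
deaths,male,2017,17159
dalys,male,2017,468246
ylls,male,2017,427223
ylds,male,2017,41024
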