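cohort,n,decile,expected,actual,printed_gap,printed_pct
all,5472629,1,2066,4219,-2153,-104
all,5472629,2,4521,5221,-700,-15
all,5472629,3,5706,6203,-498,-9
all,5472629,4,7372,7002,370,5
all,5472629,5,8962,9651,-689,-8
all,5472629,6,10668,9595,1073,10
all,5472629,7,12705,11370,1335,11
all,5472629,8,15319,13349,1970,13
all,5472629,9,19371,18681,690,4
all,5472629,10,35499,36743,-1244,-4
diabetes,1232297,1,6213,7091,-878,-14
diabetes,1232297,2,7548,7297,250,3
diabetes,1232297,3,9002,9338,-336,-4
diabetes,1232297,4,11062,11030,31,0
diabetes,1232297,5,12678,12436,242,2
diabetes,1232297,6,14840,14611,229,2
diabetes,1232297,7,17427,16800,627,4
diabetes,1232297,8,21168,20760,408,2
diabetes,1232297,9,27616,28066,-450,-2
diabetes,1232297,10,49231,52938,-3707,-8
mental_health,1958978,1,2011,5349,-3337,-166
mental_health,1958978,2,4565,6994,-2429,-53
mental_health,1958978,3,5613,7379,-1766,-31
mental_health,1958978,4,7194,8830,-1636,-23
mental_health,1958978,5,8760,10921,-2161,-25
mental_health,1958978,6,10682,11591,-909,-9
mental_health,1958978,7,12442,13276,-833,-7
mental_health,1958978,8,15276,16879,-1603,-10
mental_health,1958978,9,19488,21467,-1979,-10
mental_health,1958978,10,37307,42018,-4711,-13
dementia,157907,1,11287,13128,-1841,-16
dementia,157907,2,14928,17822,-2894,-19
dementia,157907,3,16675,20141,-3467,-21
dementia,157907,4,18828,24107,-5278,-28
dementia,157907,5,21087,27179,-6092,-29
dementia,157907,6,23562,31092,-7531,-32
dementia,157907,7,26788,35853,-9065,-34
dementia,157907,8,31380,42682,-11302,-36
dementia,157907,9,39198,50713,-11515,-29
dementia,157907,10,63859,76673,-12813,-20
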