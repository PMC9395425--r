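sex,age_years,L,M,S
F,5,-1.6,14.6,0.095
F,5.25,-1.6,14.69575,0.095875
F,5.5,-1.6,14.793,0.09675
F,5.75,-1.6,14.89175,0.097625
F,6,-1.6,14.992,0.0985
F,6.25,-1.6,15.09375,0.099375
F,6.5,-1.6,15.197,0.10025
F,6.75,-1.6,15.30175,0.101125
F,7,-1.6,15.408,0.10200000000000001
F,7.25,-1.6,15.51575,0.102875
F,7.5,-1.6,15.624999999999998,0.10375000000000001
F,7.75,-1.6,15.73575,0.104625
F,8,-1.6,15.848,0.1055
F,8.25,-1.6,15.961749999999999,0.106375
F,8.5,-1.6,16.076999999999998,0.10725
F,8.75,-1.6,16.193749999999998,0.108125
F,9,-1.6,16.312,0.109
F,9.25,-1.6,16.43175,0.109875
F,9.5,-1.6,16.552999999999997,0.11075
F,9.75,-1.6,16.67575,0.111625
F,10,-1.6,16.8,0.1125
F,10.25,-1.6,16.925749999999997,0.113375
F,10.5,-1.6,17.052999999999997,0.11425
F,10.75,-1.6,17.18175,0.115125
F,11,-1.6,17.311999999999998,0.116
F,11.25,-1.6,17.44375,0.116875
F,11.5,-1.6,17.577,0.11775
F,11.75,-1.6,17.71175,0.11862500000000001
F,12,-1.6,17.848,0.1195
F,12.25,-1.6,17.98575,0.12037500000000001
F,12.5,-1.6,18.125,0.12125
F,12.75,-1.6,18.265749999999997,0.122125
F,13,-1.6,18.408,0.123
F,13.25,-1.6,18.55175,0.123875
F,13.5,-1.6,18.697,0.12475
F,13.75,-1.6,18.84375,0.125625
F,14,-1.6,18.992,0.1265
F,14.25,-1.6,19.14175,0.12737500000000002
F,14.5,-1.6,19.293,0.12825
F,14.75,-1.6,19.44575,0.129125
F,15,-1.6,19.599999999999998,0.13
F,15.25,-1.6,19.755750000000003,0.13087500000000002
F,15.5,-1.6,19.913,0.13175
F,15.75,-1.6,20.071749999999998,0.132625
F,16,-1.6,20.232,0.1335
F,16.25,-1.6,20.39375,0.134375
F,16.5,-1.6,20.557,0.13525
F,16.75,-1.6,20.721749999999997,0.136125
F,17,-1.6,20.888,0.137
F,17.25,-1.6,21.05575,0.137875
F,17.5,-1.6,21.225,0.13875
F,17.75,-1.6,21.39575,0.139625
F,18,-1.6,21.567999999999998,0.1405
M,5,-1.6,14.8,0.095
M,5.25,-1.6,14.895750000000001,0.095875
M,5.5,-1.6,14.993,0.09675
M,5.75,-1.6,15.091750000000001,0.097625
M,6,-1.6,15.192000000000002,0.0985
M,6.25,-1.6,15.293750000000001,0.099375
M,6.5,-1.6,15.397,0.10025
M,6.75,-1.6,15.50175,0.101125
M,7,-1.6,15.608,0.10200000000000001
M,7.25,-1.6,15.715750000000002,0.102875
M,7.5,-1.6,15.825,0.10375000000000001
M,7.75,-1.6,15.93575,0.104625
M,8,-1.6,16.048000000000002,0.1055
M,8.25,-1.6,16.16175,0.106375
M,8.5,-1.6,16.277,0.10725
M,8.75,-1.6,16.39375,0.108125
M,9,-1.6,16.512,0.109
M,9.25,-1.6,16.63175,0.109875
M,9.5,-1.6,16.753,0.11075
M,9.75,-1.6,16.87575,0.111625
M,10,-1.6,17,0.1125
M,10.25,-1.6,17.12575,0.113375
M,10.5,-1.6,17.253,0.11425
M,10.75,-1.6,17.38175,0.115125
M,11,-1.6,17.512,0.116
M,11.25,-1.6,17.64375,0.116875
M,11.5,-1.6,17.777,0.11775
M,11.75,-1.6,17.91175,0.11862500000000001
M,12,-1.6,18.048000000000002,0.1195
M,12.25,-1.6,18.18575,0.12037500000000001
M,12.5,-1.6,18.325000000000003,0.12125
M,12.75,-1.6,18.46575,0.122125
M,13,-1.6,18.608,0.123
M,13.25,-1.6,18.75175,0.123875
M,13.5,-1.6,18.897000000000002,0.12475
M,13.75,-1.6,19.04375,0.125625
M,14,-1.6,19.192,0.1265
M,14.25,-1.6,19.34175,0.12737500000000002
M,14.5,-1.6,19.493,0.12825
M,14.75,-1.6,19.645750000000003,0.129125
M,15,-1.6,19.8,0.13
M,15.25,-1.6,19.955750000000002,0.13087500000000002
M,15.5,-1.6,20.113,0.13175
M,15.75,-1.6,20.27175,0.132625
M,16,-1.6,20.432000000000002,0.1335
M,16.25,-1.6,20.593750000000004,0.134375
M,16.5,-1.6,20.757,0.13525
M,16.75,-1.6,20.92175,0.136125
M,17,-1.6,21.088,0.137
M,17.25,-1.6,21.255750000000003,0.137875
M,17.5,-1.6,21.425,0.13875
M,17.75,-1.6,21.59575,0.139625
M,18,-1.6,21.768,0.1405
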