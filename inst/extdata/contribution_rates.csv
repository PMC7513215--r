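method,experiment,component,rate
pca,1,1,0.5664
pca,1,2,0.0721
pca,1,3,0.0633
pca,1,4,0.0486
pca,1,5,0.0425
pca,1,6,0.0306
pca,1,7,0.0275
pca,1,8,0.0209
pca,1,9,0.0191
pca,1,10,0.0154
pca,1,11,0.0138
pca,1,12,0.0125
pca,1,13,0.0097
pca,1,14,0.0086
pca,1,15,0.0079
pca,1,16,0.0065
pca,1,17,0.0051
pca,1,18,0.0044
pca,1,19,0.0043
pca,1,20,0.0038
pca,1,21,0.0031
pca,1,22,0.0027
pca,1,23,0.0023
pca,1,24,0.0018
pca,1,25,0.0016
pca,1,26,0.0013
pca,1,27,0.0012
pca,1,28,0.0011
pca,1,29,0.0011
pca,1,30,8e-04
pca,2,1,0.6286
pca,2,2,0.096
pca,2,3,0.047
pca,2,4,0.035
pca,2,5,0.0322
pca,2,6,0.0266
pca,2,7,0.0197
pca,2,8,0.0163
pca,2,9,0.0145
pca,2,10,0.0107
pca,2,11,0.0104
pca,2,12,0.008
pca,2,13,0.0068
pca,2,14,0.006
pca,2,15,0.0056
pca,2,16,0.005
pca,2,17,0.0046
pca,2,18,0.004
pca,2,19,0.0033
pca,2,20,0.003
pca,2,21,0.0028
pca,2,22,0.0027
pca,2,23,0.0024
pca,2,24,0.0019
pca,2,25,0.0017
pca,2,26,0.0014
pca,2,27,0.0012
pca,2,28,9e-04
pca,2,29,8e-04
pca,2,30,7e-04
poly2,1,1,0.7026
poly2,1,2,0.0534
poly2,1,3,0.0412
poly2,1,4,0.0318
poly2,1,5,0.0269
poly2,1,6,0.0213
poly2,1,7,0.019
poly2,1,8,0.0157
poly2,1,9,0.0141
poly2,1,10,0.0093
poly2,1,11,0.0077
poly2,1,12,0.0073
poly2,1,13,0.0059
poly2,1,14,0.0057
poly2,1,15,0.0048
poly2,1,16,0.0037
poly2,1,17,0.0034
poly2,1,18,0.003
poly2,1,19,0.0027
poly2,1,20,0.0023
poly2,1,21,0.0019
poly2,1,22,0.0018
poly2,1,23,0.0016
poly2,1,24,0.0015
poly2,1,25,0.0013
poly2,1,26,0.0013
poly2,1,27,0.0011
poly2,1,28,0.001
poly2,1,29,9e-04
poly2,1,30,8e-04
poly2,2,1,0.7171
poly2,2,2,0.0679
poly2,2,3,0.0359
poly2,2,4,0.0313
poly2,2,5,0.0214
poly2,2,6,0.0183
poly2,2,7,0.0156
poly2,2,8,0.0131
poly2,2,9,0.0118
poly2,2,10,0.0089
poly2,2,11,0.007
poly2,2,12,0.0064
poly2,2,13,0.0052
poly2,2,14,0.0042
poly2,2,15,0.0037
poly2,2,16,0.0034
poly2,2,17,0.003
poly2,2,18,0.0028
poly2,2,19,0.0024
poly2,2,20,0.0023
poly2,2,21,0.002
poly2,2,22,0.0019
poly2,2,23,0.0017
poly2,2,24,0.0016
poly2,2,25,0.0013
poly2,2,26,0.0011
poly2,2,27,9e-04
poly2,2,28,9e-04
poly2,2,29,8e-04
poly2,2,30,6e-04
poly1,1,1,0.5977
poly1,1,2,0.0809
poly1,1,3,0.0557
poly1,1,4,0.0434
poly1,1,5,0.0355
poly1,1,6,0.0284
poly1,1,7,0.0257
poly1,1,8,0.0208
poly1,1,9,0.0197
poly1,1,10,0.0127
poly1,1,11,0.0104
poly1,1,12,0.0097
poly1,1,13,0.0087
poly1,1,14,0.0079
poly1,1,15,0.0065
poly1,1,16,0.0051
poly1,1,17,0.0044
poly1,1,18,0.0041
poly1,1,19,0.0034
poly1,1,20,0.003
poly1,1,21,0.0026
poly1,1,22,0.0022
poly1,1,23,0.0021
poly1,1,24,0.0019
poly1,1,25,0.0017
poly1,1,26,0.0016
poly1,1,27,0.0013
poly1,1,28,0.0011
poly1,1,29,0.001
poly1,1,30,9e-04
poly1,2,1,0.6255
poly1,2,2,0.1035
poly1,2,3,0.0456
poly1,2,4,0.039
poly1,2,5,0.0288
poly1,2,6,0.0255
poly1,2,7,0.0205
poly1,2,8,0.0177
poly1,2,9,0.0139
poly1,2,10,0.0112
poly1,2,11,0.0091
poly1,2,12,0.0076
poly1,2,13,0.0066
poly1,2,14,0.0055
poly1,2,15,0.0046
poly1,2,16,0.0046
poly1,2,17,0.0042
poly1,2,18,0.0042
poly1,2,19,0.0033
poly1,2,20,0.0031
poly1,2,21,0.0026
poly1,2,22,0.0025
poly1,2,23,0.0023
poly1,2,24,0.0021
poly1,2,25,0.0016
poly1,2,26,0.0013
poly1,2,27,0.0012
poly1,2,28,9e-04
poly1,2,29,8e-04
poly1,2,30,6e-04
poly05,1,1,0.5055
poly05,1,2,0.1051
poly05,1,3,0.0685
poly05,1,4,0.0552
poly05,1,5,0.0424
poly05,1,6,0.0353
poly05,1,7,0.0314
poly05,1,8,0.025
poly05,1,9,0.0238
poly05,1,10,0.0157
poly05,1,11,0.0128
poly05,1,12,0.0128
poly05,1,13,0.0107
poly05,1,14,0.0097
poly05,1,15,0.0079
poly05,1,16,0.0062
poly05,1,17,0.0054
poly05,1,18,0.0051
poly05,1,19,0.0041
poly05,1,20,0.0036
poly05,1,21,0.0032
poly05,1,22,0.0027
poly05,1,23,0.0025
poly05,1,24,0.0023
poly05,1,25,0.002
poly05,1,26,0.0019
poly05,1,27,0.0015
poly05,1,28,0.0013
poly05,1,29,0.0012
poly05,1,30,0.001
poly05,2,1,0.5343
poly05,2,2,0.1374
poly05,2,3,0.0562
poly05,2,4,0.0476
poly05,2,5,0.0366
poly05,2,6,0.033
poly05,2,7,0.0249
poly05,2,8,0.0224
poly05,2,9,0.0159
poly05,2,10,0.0135
poly05,2,11,0.0112
poly05,2,12,0.0089
poly05,2,13,0.0081
poly05,2,14,0.0069
poly05,2,15,0.0061
poly05,2,16,0.0058
poly05,2,17,0.0052
poly05,2,18,0.0051
poly05,2,19,0.0041
poly05,2,20,0.0039
poly05,2,21,0.0033
poly05,2,22,0.003
poly05,2,23,0.0028
poly05,2,24,0.0026
poly05,2,25,0.002
poly05,2,26,0.0016
poly05,2,27,0.0014
poly05,2,28,0.0011
poly05,2,29,9e-04
poly05,2,30,7e-04
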