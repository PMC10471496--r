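"R","G"
0,0
0.05,5.7471158625946e-06
0.1,8.7997194382336e-05
0.15,0.000456398076394331
0.2,0.001439113232285
0.25,0.00351107755495129
0.3,0.00734159118830175
0.35,0.0136686831855472
0.4,0.0238853173137095
0.45,0.0378606661403105
0.5,0.0605191184407766
0.55,0.0904075287679908
0.6,0.136398222843293
0.65,0.187013689616262
0.7,0.268923594033947
0.75,0.406258222517819
0.8,0.599857497149694
0.825,0.699992147439176
0.85,0.879167338247059
0.875,1.14822442336525
0.9,1.45561213920818
0.92,1.81715098268783
0.94,2.47941065506527
0.95,2.63225867990031
0.96,3.37053649262119
0.97,4.06293803124696
0.98,5.53927040363249
0.985,6.53610566938683
0.99,8.99463223880161
0.995,14.1652222367365
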