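"patient_id","tilt_deg","region","incidence_pct","aiis_type","lcea","femoral_version","acetabular_version"
1,-10,"A",63.450059,"II",42.901567,10.655764,21.688789
1,0,"A",58.944183,"II",42.901567,10.655764,21.688789
1,10,"A",35.481268,"II",42.901567,10.655764,21.688789
2,-10,"A",50.700436,"I",38.051473,20.178687,23.437075
2,0,"A",54.786351,"I",38.051473,20.178687,23.437075
2,10,"A",30.356959,"I",38.051473,20.178687,23.437075
3,-10,"A",40.172492,"II",27.420492,6.873609,3.925464
3,0,"A",29.845803,"II",27.420492,6.873609,3.925464
3,10,"A",38.635745,"II",27.420492,6.873609,3.925464
4,-10,"A",62.854462,"II",27.207579,16.513657,15.71674
4,0,"A",57.277049,"II",27.207579,16.513657,15.71674
4,10,"A",35.574885,"II",27.207579,16.513657,15.71674
5,-10,"A",63.796023,"II",19.445526,17.558738,11.621868
5,0,"A",45.338327,"II",19.445526,17.558738,11.621868
5,10,"A",64.351956,"II",19.445526,17.558738,11.621868
6,-10,"A",38.039749,"II",33.853409,26.915795,21.184565
6,0,"A",34.711438,"II",33.853409,26.915795,21.184565
6,10,"A",38.720289,"II",33.853409,26.915795,21.184565
7,-10,"A",58.713277,"II",30.805286,20.897682,22.237047
7,0,"A",64.778959,"II",30.805286,20.897682,22.237047
7,10,"A",46.607372,"II",30.805286,20.897682,22.237047
8,-10,"A",54.696478,"II",39.5997,12.96796,14.153432
8,0,"A",49.670696,"II",39.5997,12.96796,14.153432
8,10,"A",40.613082,"II",39.5997,12.96796,14.153432
9,-10,"A",54.847837,"I",35.512833,24.130587,16.790825
9,0,"A",54.786972,"I",35.512833,24.130587,16.790825
9,10,"A",43.933259,"I",35.512833,24.130587,16.790825
10,-10,"A",75.716298,"II",40.939197,11.769868,9.222213
10,0,"A",45.345013,"II",40.939197,11.769868,9.222213
10,10,"A",31.426713,"II",40.939197,11.769868,9.222213
11,-10,"A",51.514741,"II",39.451827,19.896697,11.337382
11,0,"A",49.189041,"II",39.451827,19.896697,11.337382
11,10,"A",41.149137,"II",39.451827,19.896697,11.337382
12,-10,"A",72.713212,"II",30.545564,5.573886,16.889853
12,0,"A",67.606352,"II",30.545564,5.573886,16.889853
12,10,"A",51.36639,"II",30.545564,5.573886,16.889853
13,-10,"A",49.190719,"II",28.405362,29.66687,22.293892
13,0,"A",19.698118,"II",28.405362,29.66687,22.293892
13,10,"A",9.626737,"II",28.405362,29.66687,22.293892
14,-10,"A",87.091403,"I",26.052916,-1.710325,9.773637
14,0,"A",87.231281,"I",26.052916,-1.710325,9.773637
14,10,"A",71.452766,"I",26.052916,-1.710325,9.773637
15,-10,"A",46.391924,"II",32.617198,11.624352,23.379026
15,0,"A",53.008866,"II",32.617198,11.624352,23.379026
15,10,"A",27.657537,"II",32.617198,11.624352,23.379026
16,-10,"A",13.469802,"II",25.592057,12.094216,11.965476
16,0,"A",0.946471,"II",25.592057,12.094216,11.965476
16,10,"A",0,"II",25.592057,12.094216,11.965476
17,-10,"A",69.162051,"I",27.855875,4.978659,19.678515
17,0,"A",72.263479,"I",27.855875,4.978659,19.678515
17,10,"A",62.579883,"I",27.855875,4.978659,19.678515
18,-10,"A",100,"I",39.710705,14.823766,25.79299
18,0,"A",88.697556,"I",39.710705,14.823766,25.79299
18,10,"A",75.552755,"I",39.710705,14.823766,25.79299
19,-10,"A",57.184638,"II",34.028326,5.326453,26.0714
19,0,"A",65.115346,"II",34.028326,5.326453,26.0714
19,10,"A",45.797428,"II",34.028326,5.326453,26.0714
20,-10,"A",73.659955,"II",25.435703,-8.035337,15.917347
20,0,"A",63.861346,"II",25.435703,-8.035337,15.917347
20,10,"A",42.242389,"II",25.435703,-8.035337,15.917347
21,-10,"A",59.128672,"II",32.525831,12.414889,16.982855
21,0,"A",58.839117,"II",32.525831,12.414889,16.982855
21,10,"A",33.031024,"II",32.525831,12.414889,16.982855
22,-10,"A",48.537829,"I",26.891036,21.87038,9.683163
22,0,"A",48.889941,"I",26.891036,21.87038,9.683163
22,10,"A",24.887519,"I",26.891036,21.87038,9.683163
23,-10,"A",49.8479,"II",44.744336,11.285091,14.563793
23,0,"A",16.613024,"II",44.744336,11.285091,14.563793
23,10,"A",33.029942,"II",44.744336,11.285091,14.563793
24,-10,"A",42.051668,"II",38.451504,-1.678912,19.342981
24,0,"A",44.464685,"II",38.451504,-1.678912,19.342981
24,10,"A",43.006266,"II",38.451504,-1.678912,19.342981
25,-10,"A",53.639228,"II",35.661284,22.259684,21.309311
25,0,"A",32.990526,"II",35.661284,22.259684,21.309311
25,10,"A",36.504884,"II",35.661284,22.259684,21.309311
26,-10,"A",95.231417,"I",29.260168,-1.09863,21.082536
26,0,"A",71.688971,"I",29.260168,-1.09863,21.082536
26,10,"A",55.57364,"I",29.260168,-1.09863,21.082536
27,-10,"A",41.816943,"II",31.344905,19.253013,14.269359
27,0,"A",20.270355,"II",31.344905,19.253013,14.269359
27,10,"A",24.02296,"II",31.344905,19.253013,14.269359
28,-10,"A",40.872667,"I",16.466505,12.89657,19.574042
28,0,"A",30.138735,"I",16.466505,12.89657,19.574042
28,10,"A",30.362837,"I",16.466505,12.89657,19.574042
29,-10,"A",61.250354,"I",27.713563,19.25487,18.264501
29,0,"A",56.756458,"I",27.713563,19.25487,18.264501
29,10,"A",30.41824,"I",27.713563,19.25487,18.264501
30,-10,"A",38.182997,"I",41.813037,19.58979,18.15562
30,0,"A",23.663821,"I",41.813037,19.58979,18.15562
30,10,"A",20.628476,"I",41.813037,19.58979,18.15562
31,-10,"A",71.689942,"II",27.050118,23.891119,28.20275
31,0,"A",45.934,"II",27.050118,23.891119,28.20275
31,10,"A",36.6958,"II",27.050118,23.891119,28.20275
32,-10,"A",34.843416,"I",30.463833,17.216008,28.900401
32,0,"A",44.988925,"I",30.463833,17.216008,28.900401
32,10,"A",54.644652,"I",30.463833,17.216008,28.900401
33,-10,"A",73.562567,"I",29.741777,25.115265,25.941023
33,0,"A",67.774078,"I",29.741777,25.115265,25.941023
33,10,"A",49.026063,"I",29.741777,25.115265,25.941023
34,-10,"A",94.83958,"II",41.264688,-8.282474,18.137993
34,0,"A",82.95566,"II",41.264688,-8.282474,18.137993
34,10,"A",82.278632,"II",41.264688,-8.282474,18.137993
35,-10,"A",76.673579,"I",35.804682,27.088011,7.097955
35,0,"A",43.894462,"I",35.804682,27.088011,7.097955
35,10,"A",52.972714,"I",35.804682,27.088011,7.097955
36,-10,"A",85.403526,"II",25.715828,6.337783,12.052601
36,0,"A",60.027285,"II",25.715828,6.337783,12.052601
36,10,"A",68.491948,"II",25.715828,6.337783,12.052601
37,-10,"A",64.260219,"I",26.639033,16.010944,20.547801
37,0,"A",52.053875,"I",26.639033,16.010944,20.547801
37,10,"A",41.476605,"I",26.639033,16.010944,20.547801
38,-10,"A",45.895254,"II",25.331662,24.166433,10.527821
38,0,"A",46.980076,"II",25.331662,24.166433,10.527821
38,10,"A",38.147509,"II",25.331662,24.166433,10.527821
39,-10,"A",91.61778,"II",26.898212,-3.930196,19.50707
39,0,"A",68.709858,"II",26.898212,-3.930196,19.50707
39,10,"A",67.95705,"II",26.898212,-3.930196,19.50707
40,-10,"A",56.857931,"II",37.196109,19.051405,18.306761
40,0,"A",34.623846,"II",37.196109,19.051405,18.306761
40,10,"A",25.752892,"II",37.196109,19.051405,18.306761
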