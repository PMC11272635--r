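"patient_id","tilt_deg","region","incidence_pct","aiis_type","lcea","femoral_version","acetabular_version"
1,-10,"A",38.485878,"II",37.865863,10.43303,14.386268
1,0,"A",28.714358,"II",37.865863,10.43303,14.386268
1,10,"A",34.33248,"II",37.865863,10.43303,14.386268
2,-10,"A",39.187732,"I",32.132162,20.993573,11.135697
2,0,"A",62.265484,"I",32.132162,20.993573,11.135697
2,10,"A",39.530017,"I",32.132162,20.993573,11.135697
3,-10,"A",24.899433,"II",27.152863,21.168609,23.738791
3,0,"A",34.65042,"II",27.152863,21.168609,23.738791
3,10,"A",34.819815,"II",27.152863,21.168609,23.738791
4,-10,"A",28.375713,"II",33.116948,10.801889,10.465834
4,0,"A",28.732368,"II",33.116948,10.801889,10.465834
4,10,"A",59.892266,"II",33.116948,10.801889,10.465834
5,-10,"A",45.377413,"II",41.458285,25.65743,16.781907
5,0,"A",54.683921,"II",41.458285,25.65743,16.781907
5,10,"A",57.932887,"II",41.458285,25.65743,16.781907
6,-10,"A",31.067698,"I",30.911693,17.661045,26.897104
6,0,"A",23.399836,"I",30.911693,17.661045,26.897104
6,10,"A",35.727983,"I",30.911693,17.661045,26.897104
7,-10,"A",56.564095,"I",35.723063,13.531718,11.993773
7,0,"A",59.861243,"I",35.723063,13.531718,11.993773
7,10,"A",39.311905,"I",35.723063,13.531718,11.993773
8,-10,"A",27.540231,"II",21.853364,29.887506,14.639407
8,0,"A",56.081129,"II",21.853364,29.887506,14.639407
8,10,"A",55.499759,"II",21.853364,29.887506,14.639407
9,-10,"A",36.563854,"II",26.782592,20.521306,17.718025
9,0,"A",34.819146,"II",26.782592,20.521306,17.718025
9,10,"A",38.345481,"II",26.782592,20.521306,17.718025
10,-10,"A",31.262779,"I",29.383057,8.290632,22.3872
10,0,"A",54.283993,"I",29.383057,8.290632,22.3872
10,10,"A",51.353374,"I",29.383057,8.290632,22.3872
11,-10,"A",40.456341,"II",26.326006,24.281292,18.193692
11,0,"A",48.269132,"II",26.326006,24.281292,18.193692
11,10,"A",49.3344,"II",26.326006,24.281292,18.193692
12,-10,"A",47.275672,"II",31.206609,11.309505,14.672562
12,0,"A",68.254948,"II",31.206609,11.309505,14.672562
12,10,"A",42.034613,"II",31.206609,11.309505,14.672562
13,-10,"A",67.99265,"I",24.818653,20.262757,20.828848
13,0,"A",49.943439,"I",24.818653,20.262757,20.828848
13,10,"A",75.304158,"I",24.818653,20.262757,20.828848
14,-10,"A",57.514024,"II",32.72482,12.312499,25.684833
14,0,"A",36.572108,"II",32.72482,12.312499,25.684833
14,10,"A",50.693597,"II",32.72482,12.312499,25.684833
15,-10,"A",62.321302,"I",25.943328,12.46308,13.486497
15,0,"A",57.827395,"I",25.943328,12.46308,13.486497
15,10,"A",67.501189,"I",25.943328,12.46308,13.486497
16,-10,"A",20.571437,"II",41.276519,11.481722,16.197769
16,0,"A",33.088814,"II",41.276519,11.481722,16.197769
16,10,"A",36.151734,"II",41.276519,11.481722,16.197769
17,-10,"A",33.343201,"I",31.882197,27.10033,25.967522
17,0,"A",38.369989,"I",31.882197,27.10033,25.967522
17,10,"A",10.118012,"I",31.882197,27.10033,25.967522
18,-10,"A",36.378432,"II",40.54347,-3.615373,12.170866
18,0,"A",52.857507,"II",40.54347,-3.615373,12.170866
18,10,"A",27.175524,"II",40.54347,-3.615373,12.170866
19,-10,"A",39.255743,"II",29.143517,1.149321,24.846203
19,0,"A",42.452108,"II",29.143517,1.149321,24.846203
19,10,"A",60.949602,"II",29.143517,1.149321,24.846203
20,-10,"A",22.151117,"II",38.02448,8.355941,19.529776
20,0,"A",23.02334,"II",38.02448,8.355941,19.529776
20,10,"A",29.264631,"II",38.02448,8.355941,19.529776
21,-10,"A",35.602621,"II",36.075087,8.217004,12.656186
21,0,"A",26.299844,"II",36.075087,8.217004,12.656186
21,10,"A",42.312479,"II",36.075087,8.217004,12.656186
22,-10,"A",45.141785,"II",29.070601,12.585184,12.684688
22,0,"A",45.583511,"II",29.070601,12.585184,12.684688
22,10,"A",55.917775,"II",29.070601,12.585184,12.684688
23,-10,"A",36.944637,"I",29.058926,8.543861,24.36065
23,0,"A",39.398773,"I",29.058926,8.543861,24.36065
23,10,"A",54.167336,"I",29.058926,8.543861,24.36065
24,-10,"A",31.672354,"I",37.242084,-2.770216,20.969977
24,0,"A",32.244374,"I",37.242084,-2.770216,20.969977
24,10,"A",25.153873,"I",37.242084,-2.770216,20.969977
25,-10,"A",44.915199,"II",31.46029,23.468404,20.613125
25,0,"A",53.819637,"II",31.46029,23.468404,20.613125
25,10,"A",68.089249,"II",31.46029,23.468404,20.613125
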