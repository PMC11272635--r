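"patient_id","tilt_deg","region","incidence_pct","aiis_type","lcea","femoral_version","acetabular_version"
1,-10,"A",77.609706,"II",26.332302,16.146868,27.277872
1,0,"A",57.623607,"II",26.332302,16.146868,27.277872
1,10,"A",15.14469,"II",26.332302,16.146868,27.277872
2,-10,"A",47.965525,"II",27.040973,22.696517,18.224561
2,0,"A",28.626934,"II",27.040973,22.696517,18.224561
2,10,"A",43.875432,"II",27.040973,22.696517,18.224561
3,-10,"A",64.306771,"II",32.247517,-0.478304,11.658764
3,0,"A",60.525785,"II",32.247517,-0.478304,11.658764
3,10,"A",45.556492,"II",32.247517,-0.478304,11.658764
4,-10,"A",67.395835,"II",42.624639,35.688953,17.645423
4,0,"A",62.967585,"II",42.624639,35.688953,17.645423
4,10,"A",42.359801,"II",42.624639,35.688953,17.645423
5,-10,"A",56.649475,"II",43.492986,27.615033,26.231816
5,0,"A",36.324102,"II",43.492986,27.615033,26.231816
5,10,"A",16.959748,"II",43.492986,27.615033,26.231816
6,-10,"A",51.951229,"II",36.143448,27.204693,32.051662
6,0,"A",33.53212,"II",36.143448,27.204693,32.051662
6,10,"A",32.222702,"II",36.143448,27.204693,32.051662
7,-10,"A",60.292402,"II",29.454928,23.904265,29.518974
7,0,"A",74.668848,"II",29.454928,23.904265,29.518974
7,10,"A",12.028357,"II",29.454928,23.904265,29.518974
8,-10,"A",63.003172,"II",25.653197,16.939997,16.333774
8,0,"A",45.410144,"II",25.653197,16.939997,16.333774
8,10,"A",59.936839,"II",25.653197,16.939997,16.333774
9,-10,"A",80.145309,"I",31.12224,20.147668,18.835873
9,0,"A",47.359451,"I",31.12224,20.147668,18.835873
9,10,"A",41.427079,"I",31.12224,20.147668,18.835873
10,-10,"A",62.713648,"I",34.504758,34.822542,38.374873
10,0,"A",63.541087,"I",34.504758,34.822542,38.374873
10,10,"A",29.01574,"I",34.504758,34.822542,38.374873
11,-10,"A",53.835644,"II",27.737226,29.848744,21.212925
11,0,"A",62.312238,"II",27.737226,29.848744,21.212925
11,10,"A",38.41747,"II",27.737226,29.848744,21.212925
12,-10,"A",60.661608,"I",33.072546,15.439806,18.936282
12,0,"A",42.438303,"I",33.072546,15.439806,18.936282
12,10,"A",21.875923,"I",33.072546,15.439806,18.936282
13,-10,"A",67.659742,"II",27.110476,7.390566,12.859759
13,0,"A",47.040728,"II",27.110476,7.390566,12.859759
13,10,"A",31.413472,"II",27.110476,7.390566,12.859759
14,-10,"A",88.052857,"II",30.802066,0.428742,16.904521
14,0,"A",41.426837,"II",30.802066,0.428742,16.904521
14,10,"A",62.022467,"II",30.802066,0.428742,16.904521
15,-10,"A",86.2954,"II",38.476076,11.72043,21.195728
15,0,"A",90.919648,"II",38.476076,11.72043,21.195728
15,10,"A",57.555519,"II",38.476076,11.72043,21.195728
16,-10,"A",55.047866,"II",43.905779,11.366307,12.303561
16,0,"A",70.622649,"II",43.905779,11.366307,12.303561
16,10,"A",51.217002,"II",43.905779,11.366307,12.303561
17,-10,"A",80.850169,"II",20.50924,-2.873713,35.979098
17,0,"A",65.704487,"II",20.50924,-2.873713,35.979098
17,10,"A",50.036227,"II",20.50924,-2.873713,35.979098
18,-10,"A",37.533529,"II",29.776218,33.20796,11.52571
18,0,"A",48.076787,"II",29.776218,33.20796,11.52571
18,10,"A",29.240965,"II",29.776218,33.20796,11.52571
19,-10,"A",70.959699,"I",29.849481,-4.002893,21.374741
19,0,"A",62.875563,"I",29.849481,-4.002893,21.374741
19,10,"A",16.337645,"I",29.849481,-4.002893,21.374741
20,-10,"A",63.47589,"II",29.339339,19.947606,15.043607
20,0,"A",56.663091,"II",29.339339,19.947606,15.043607
20,10,"A",37.925943,"II",29.339339,19.947606,15.043607
21,-10,"A",82.269005,"I",31.077169,22.348103,27.46612
21,0,"A",53.522078,"I",31.077169,22.348103,27.46612
21,10,"A",33.700255,"I",31.077169,22.348103,27.46612
22,-10,"A",83.874922,"II",19.252805,11.910599,25.498708
22,0,"A",36.147923,"II",19.252805,11.910599,25.498708
22,10,"A",24.676232,"II",19.252805,11.910599,25.498708
23,-10,"A",65.200298,"II",19.369301,-0.110195,10.82306
23,0,"A",36.70012,"II",19.369301,-0.110195,10.82306
23,10,"A",41.976699,"II",19.369301,-0.110195,10.82306
24,-10,"A",55.870601,"II",29.0188,3.551726,18.089034
24,0,"A",56.279327,"II",29.0188,3.551726,18.089034
24,10,"A",51.457615,"II",29.0188,3.551726,18.089034
25,-10,"A",63.758438,"II",36.361975,10.321642,13.822209
25,0,"A",27.766444,"II",36.361975,10.321642,13.822209
25,10,"A",16.969583,"II",36.361975,10.321642,13.822209
26,-10,"A",29.818538,"II",28.738635,12.181695,22.006064
26,0,"A",24.70495,"II",28.738635,12.181695,22.006064
26,10,"A",31.024837,"II",28.738635,12.181695,22.006064
27,-10,"A",55.443016,"II",18.861984,15.082832,16.017803
27,0,"A",42.973454,"II",18.861984,15.082832,16.017803
27,10,"A",46.429623,"II",18.861984,15.082832,16.017803
28,-10,"A",63.842492,"II",30.723206,16.07072,28.691908
28,0,"A",43.879591,"II",30.723206,16.07072,28.691908
28,10,"A",16.911841,"II",30.723206,16.07072,28.691908
29,-10,"A",73.138402,"II",26.160414,26.027812,14.918392
29,0,"A",66.808549,"II",26.160414,26.027812,14.918392
29,10,"A",29.052304,"II",26.160414,26.027812,14.918392
30,-10,"A",42.197425,"II",31.732463,36.001548,18.836219
30,0,"A",51.216238,"II",31.732463,36.001548,18.836219
30,10,"A",24.340907,"II",31.732463,36.001548,18.836219
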