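age,residual_expectancy
0,88.9
1,88.0
5,84.0
10,79.1
15,74.1
20,69.2
25,64.3
30,59.3
35,54.4
40,49.5
45,44.7
50,39.9
55,35.1
60,30.5
65,26.0
70,21.6
75,17.5
80,13.7
85,10.3
90,7.6
95,5.8
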