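population,country,X,Y,n
1,Portugal,-8.18,37.24,9
2,Portugal,-7.66,37.33,10
3,Portugal,-8.67,37.77,15
4,Portugal,-8.42,39.73,10
5,Spain,2.02,41.33,10
6,Spain,2.73,41.65,9
7,Spain,2.51,42.04,10
8,Spain,2.87,42.00,13
9,France,0.35,45.04,5
10,Switzerland,6.52,46.79,7
11,Italy,10.73,43.40,14
12,Italy,11.67,44.26,12
13,Italy,12.44,43.94,15
14,Croatia,15.66,44.14,6
15,Croatia,16.37,43.99,11
16,Croatia,16.10,43.78,13
17,Croatia,16.67,43.79,9
18,Slovakia,20.18,48.62,9
19,Slovakia,20.95,48.62,9
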