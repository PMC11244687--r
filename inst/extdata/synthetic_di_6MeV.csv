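"depth_cm","value"
0,41.8072
0.1,47.7104
0.2,53.8602
0.3,60.1474
0.4,66.4445
0.5,72.6098
0.6,78.4919
0.7,83.936
0.8,88.7902
0.9,92.9128
1,96.1789
1.1,98.4867
1.2,99.7629
1.3,99.9664
1.4,99.0907
1.5,97.164
1.6,94.2478
1.7,90.4338
1.8,85.8389
1.9,80.5993
2,74.8638
2.1,68.7869
2.2,62.5221
2.3,56.2154
2.4,50
2.5,43.9925
2.6,38.2896
2.7,32.9668
2.8,28.078
2.9,23.6565
3,19.7164
3.1,16.2554
3.2,13.2575
3.3,10.6959
3.4,8.5363
3.5,6.7393
3.6,5.2633
3.7,4.0662
3.8,3.1075
3.9,2.3493
4,1.7569
4.1,1.2997
4.2,0.9512
4.3,0.6886
4.4,0.4931
4.5,0.3493
4.6,0.2448
4.7,0.1697
4.8,0.1164
4.9,0.0789
5,0.053
5.1,0.0352
5.2,0.0231
5.3,0.015
5.4,0.0096
5.5,0.0061
5.6,0.0039
5.7,0.0024
5.8,0.0015
5.9,9e-04
6,5e-04
6.1,3e-04
6.2,2e-04
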