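subject,age,sex,V1,V2,y1,y2
1,0,F,63.76,38.16,3.14,47.82
2,4,M,100.88,41.46,4.87,64.02
1,6,F,60.98,41.37,8.43,73.21
3,0,M,93.24,48.76,2.82,44.93
2,7,M,101.95,44.79,8.03,89.54
2,10,M,99.24,48.17,10.08,92.14
1,16,F,,44.79,13.96,86.12
3,9,M,88.38,47.91,8.47,86.42
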