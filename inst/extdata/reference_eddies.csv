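flow_rate_ml_min,reynolds,condition,largest_eddy_mm
1,2.7,Unbaffled,3.1
1,2.7,3 x 2,2.9
1,2.7,3 x 4,6.3
1,2.7,9 x 2,3.0
1,2.7,9 x 4,4.2
1,2.7,Top 9 x 2,3.1
1,2.7,Top 9 x 4,19.9
1,2.7,Top against flow,25.4
1,2.7,Top against flow with gradient,6.0
1,2.7,Top with flow,4.0
1,2.7,Top with flow with gradient,3.7
10,27,Unbaffled,40.6
10,27,3 x 2,44.4
10,27,3 x 4,37.2
10,27,9 x 2,31.3
10,27,9 x 4,29.4
10,27,Top 9 x 2,37.7
10,27,Top 9 x 4,20.8
10,27,Top against flow,41.3
10,27,Top against flow with gradient,42.0
10,27,Top with flow,42.6
10,27,Top with flow with gradient,41.8
100,270,Unbaffled,34.6
100,270,3 x 2,28.3
100,270,3 x 4,31.8
100,270,9 x 2,38.7
100,270,9 x 4,17.8
100,270,Top 9 x 2,34.4
100,270,Top 9 x 4,30.5
100,270,Top against flow,27.1
100,270,Top against flow with gradient,34.2
100,270,Top with flow,34.9
100,270,Top with flow with gradient,31.7
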