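label,energy_mev,applicator_cm,ssd_cm,dmax_cm,measured_factor,calculated_factor,percent_difference
3 x 4,6,6,100,1.2,0.935,0.946,1.2
4.5 x 3.5,6,6,100,1.3,0.979,0.975,-0.4
3 x 3.5,6,6,100,1.1,0.924,0.936,1.3
C5,6,6,105,1.3,0.986,0.98,-0.6
6 x 5,6,10,105,1.2,0.995,0.983,-1.2
6 x 8,6,10,110,1.2,0.986,0.984,-0.2
6 x 12,6,15,110,1.2,0.981,0.981,0.0
4 x 17,6,20,100,1.2,0.987,0.975,-1.2
4 x 17,6,20,110,1.2,0.898,0.887,-1.2
C5,9,6,100,2.0,0.982,0.98,-0.2
4.5 x 3.5,9,6,105,1.8,0.944,0.94,-0.4
3 x 3.5,9,6,105,1.5,0.865,0.870,0.7
7 x 9,9,10,100,2.0,1.006,1.006,0.0
C7,9,10,105,2.0,0.999,0.994,-0.5
C10,9,15,105,2.0,1.006,0.999,-0.7
7 x 19,9,20,105,2.0,0.996,0.996,0.0
5 x 8,12,10,105,2.7,0.983,0.983,0.0
8 x 14,12,15,110,2.8,1.001,1.007,0.6
7 x 10,12,10,105,2.8,1.000,1.006,0.6
C7,12,10,100,2.8,0.998,0.994,-0.4
6 x 10,16,10,100,2.8,1.005,1.001,-0.4
7 x 9,16,10,105,3.2,1.001,1.000,-0.1
7 x 14,16,15,100,3.2,1.008,1.018,1.0
9 x 19,16,20,100,3.2,1.013,1.015,0.2
6 x 8,20,10,105,2.0,1.001,0.997,-0.4
8 x 14,20,15,110,2.8,1.000,1.006,0.6
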