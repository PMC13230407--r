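region,A,B,C,D,E,F,G,total
Alpine,5.2,12.9,14.8,42.5,31.4,41.6,13.7,162
Alpine-Scandinavian,24.8,1.1,26.3,27.0,5.4,0.2,0.0,85
Arctic,0.02,0.001,0.05,0.03,0,0,0,0.1
Atlantic,2.1,1.6,12.8,86.6,31.3,32.0,15.8,182
Black Sea,0.1,0.2,0.1,0.7,1.4,0.03,0,3
Boreal,30.0,4.9,42.5,127.1,136.6,190.5,47.8,579
Continental,4.9,6.5,4.2,100.9,82.6,111.2,80.9,391
Mediterranean,7.6,12.1,15.9,236.3,20.4,9.9,0.7,303
Pannonian,0.7,0.4,0.2,7.9,8.1,7.2,0.9,25
Steppic,0.1,0.04,0.01,0.9,0.9,0.3,0.0,2
Total,75.5,39.8,116.9,630.0,318.1,392.9,159.9,1733
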