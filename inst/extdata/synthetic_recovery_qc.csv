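name,sd_recovery,mean_concentration,spike
pfoa,0.157,2.1,50
pfos,0.139,10.3,50
pfhxs,0.252,1.2,50
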