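label,events_trt,total_trt,events_ctl,total_ctl
synth_trial_1,12,100,20,100
synth_trial_2,8,60,9,55
synth_trial_3,0,40,4,42
synth_trial_4,15,120,14,118
synth_trial_5,3,30,7,32
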