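study,effect,se
trial_01,0.427,0.201
trial_02,0.334,0.272
trial_03,0.231,0.14
trial_04,0.212,0.275
trial_05,0.458,0.144
trial_06,0.483,0.173
trial_07,0.346,0.129
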