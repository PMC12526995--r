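table,case,quantity,printed,expected_fail
integration,case1,mean,0.558,0
integration,case1,sd,0.179,0
integration,case1,ci95,0.150,0
integration,case2,mean,0.808,0
integration,case2,sd,0.206,0
integration,case2,ci95,0.172,0
integration,case3,mean,1.305,0
integration,case3,sd,0.214,0
integration,case3,ci95,0.179,0
regression,case1,mean,0.506,0
regression,case1,sd,0.123,0
regression,case1,ci95,0.103,0
regression,case2,mean,0.569,0
regression,case2,sd,0.169,0
regression,case2,ci95,0.141,0
regression,case3,mean,0.533,0
regression,case3,sd,0.184,0
regression,case3,ci95,0.154,0
cnn_stft,case1,mean,0.443,0
cnn_stft,case1,sd,0.161,0
cnn_stft,case1,ci95,0.135,0
cnn_stft,case2,mean,0.561,0
cnn_stft,case2,sd,0.169,1
cnn_stft,case2,ci95,0.141,1
cnn_stft,case3,mean,0.511,0
cnn_stft,case3,sd,0.184,1
cnn_stft,case3,ci95,0.154,1
cnn_wvd,case1,mean,0.407,0
cnn_wvd,case1,sd,0.165,0
cnn_wvd,case1,ci95,0.138,0
cnn_wvd,case2,mean,0.448,0
cnn_wvd,case2,sd,0.129,0
cnn_wvd,case2,ci95,0.108,0
cnn_wvd,case3,mean,0.489,1
cnn_wvd,case3,sd,0.128,0
cnn_wvd,case3,ci95,0.107,0
grand,all,mean_cnn_stft,0.505,0
grand,all,mean_cnn_wvd,0.447,0
grand,all,improvement_pct,11.5,0
paired_t,all,t,1.4867,0
paired_t,all,p,0.1507,0
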