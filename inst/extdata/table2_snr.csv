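sample,xineos_snr_beta0,xineos_snr_beta_retr,xineos_gain3d,eiger_snr_beta0,eiger_snr_beta_retr,eiger_gain3d
1,3.1,13.2,4.5,0.5,5.9,10.9
2,2.9,12.2,4.3,0.5,5.7,11.0
3,3.0,12.4,4.0,0.5,5.6,10.8
4,2.8,11.8,4.2,0.5,5.5,10.7
5,2.7,11.7,4.3,0.5,5.6,10.9
6,2.7,11.9,4.3,0.5,5.6,10.7
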