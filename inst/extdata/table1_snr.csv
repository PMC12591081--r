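sample,xineos_snr0,xineos_snr_retr,xineos_gain2d,eiger_snr0,eiger_snr_retr,eiger_gain2d
1,85.7,162.2,1.9,33.9,140.0,4.1
2,84.7,156.0,1.8,33.8,141.2,4.2
3,83.3,147.6,1.8,33.7,140.5,4.2
4,86.8,168.3,1.9,33.5,140.0,4.2
5,85.6,163.9,1.9,33.3,139.0,4.2
6,87.6,171.8,2.0,33.5,143.0,4.3
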