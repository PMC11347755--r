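(sp3:1,(sp5:0.8,(((sp1:0.2,sp6:0.2):0.2,sp4:0.4):0.2,sp2:0.6):0.2):0.2);
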