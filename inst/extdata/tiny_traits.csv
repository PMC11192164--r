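site,source,plot,height_cm,alive
MD,XCS,PL1,28.1,1
MD,XCS,PL1,27.3,1
MD,XCS,PL1,,0
MD,XDS,PL2,25.0,1
MD,XDS,PL2,24.2,true
MD,XDS,PL2,,false
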