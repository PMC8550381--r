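species,total_length_cm,body_depth_pct,ecotype,farming
sp01,5.2,42.1,benthic,1
sp02,6.0,45.3,benthic,1
sp03,7.1,39.8,intermediate,0
sp04,8.3,44.0,intermediate,0
sp05,9.9,47.6,benthic,0
sp06,11.2,36.2,intermediate,0
sp07,12.5,33.4,pelagic,0
sp08,13.8,30.9,pelagic,0
sp09,21.5,52.3,benthic,0
sp10,27.0,55.1,benthic,0
sp11,16.4,,pelagic,0
sp12,,48.2,intermediate,0
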