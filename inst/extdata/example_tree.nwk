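((sp03:0.640347581298,((sp07:0.428313714272,(sp06:0.00932121729873,sp12:0.00932121729873):0.418992496973):0.0743643880246,sp01:0.502678102297):0.137669479002):1.28822877754,((sp05:0.195321139068,sp11:0.195321139068):1.57783921146,((sp08:0.486090868124,sp09:0.486090868124):0.393138422034,(sp02:0.804615095936,(sp04:0.346694301716,sp10:0.346694301716):0.457920794219):0.0746141942218):0.893931060367):0.155416008318);
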