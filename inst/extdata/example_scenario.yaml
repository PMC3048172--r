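# example scenario configuration: a slow-cycling tumor given the default
# preoperative protocol, 10 cm^3 at diagnosis
name: example
Tc: 32
P_sym: 0.5
P_sleep: 0.3
volume_cm3: 10
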