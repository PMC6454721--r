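drug_a,drug_b,sign
d01,d02,+1
d01,d03,+1
d01,d04,+1
d01,d05,-1
d02,d03,+1
d02,d04,+1
d02,d06,-1
d03,d04,+1
d03,d05,+1
d04,d09,-1
d04,d10,-1
d04,d11,-1
d04,d12,-1
d05,d06,+1
d05,d07,+1
d05,d08,+1
d06,d07,+1
d06,d08,+1
d07,d08,+1
d07,d13,-1
d08,d13,-1
d09,d10,-1
d09,d11,-1
d09,d12,-1
d09,d13,-1
d10,d11,-1
d10,d12,-1
d10,d13,-1
d11,d12,-1
d11,d13,-1
d12,d13,-1
d13,d14,+1
d13,d15,+1
d14,d15,+1
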