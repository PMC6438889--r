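{"partition":[1,1,1,1,2,2,2,3,3,3],"hub_nodes":{"A":1,"B":[]},"edge_effects":[],"seed":60924}
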