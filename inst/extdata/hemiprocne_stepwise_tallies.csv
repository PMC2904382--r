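"series","n_molting","n_stepwise","n_feathers"
"primaries",166,35,10
"outer_secondaries",39,5,7
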