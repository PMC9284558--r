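# tempogate CRN v1
fidelity abstract
species A ; role=input ; composition=A
species B ; role=input ; composition=B
species a ; role=memory ; composition=A
species b ; role=memory ; composition=B
species Y ; role=output ; composition=A+B
species Z ; role=output ; composition=A+B
reaction A -> a ; k=             0.002 ; units=/s ; label=memory_A
reaction B -> b ; k=             0.002 ; units=/s ; label=memory_B
reaction a + B -> Y ; k=           2000000 ; units=/M/s ; label=output_Y
reaction A + b -> Z ; k=           2000000 ; units=/M/s ; label=output_Z
meta {"type":"list","attributes":{"names":{"type":"character","attributes":{},"value":["inputs","outputs","output_of_first","input_conc","memory_timescale"]}},"value":[{"type":"character","attributes":{},"value":["A","B"]},{"type":"character","attributes":{"names":{"type":"character","attributes":{},"value":["Y","Z"]}},"value":["Y","Z"]},{"type":"character","attributes":{"names":{"type":"character","attributes":{},"value":["A","B"]}},"value":["Y","Z"]},{"type":"double","attributes":{},"value":[100]},{"type":"double","attributes":{},"value":[500]}]}
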