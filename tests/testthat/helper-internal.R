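# internal helpers reused by the tests
with_seed <- histomamba:::with_seed
ag_tape_begin <- histomamba:::ag_tape_begin
ag_tape_end <- histomamba:::ag_tape_end
ag_backward <- histomamba:::ag_backward
ag_value <- histomamba:::ag_value
training_graph <- histomamba:::training_graph
model_graph <- histomamba:::model_graph
block_forward <- histomamba:::block_forward
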