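"cell_id","capture_frame","frame_interval","termination","termination_frame"
"S2cell",0,10,"death_called",291
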