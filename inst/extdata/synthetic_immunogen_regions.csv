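antibody,source_id,start,end,target_id
anti-TRPA1-N100,TRPA1_HUMAN_SYNTHETIC,1,100,TRPA1_MOUSE_SYNTHETIC
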