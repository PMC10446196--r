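question_id,accepted
sb_weak,the man
sb_attention,strongly agree
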