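{"fs_hz":100,"channel":"PPG","subject_id":"S05","t0":0}
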