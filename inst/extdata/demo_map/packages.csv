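package_id,name,member_prefix
heart_failure,Heart failure,I50
acute_kidney_failure,Acute kidney failure,N19
acute_kidney_failure,Acute kidney failure,N170
acute_kidney_failure,Acute kidney failure,N179
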