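cause,sex
cervical_cancer,female
uterine_cancer,female
breast_cancer,female
prostate_cancer,male
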