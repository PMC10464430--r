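record_id,code,role
d001,I25.1,associated
d001,E11.9,associated
d002,I50.9,immediate
d004,C34.9,associated
d004,I10,associated
d006,T40.1,intermediate
d007,J44.9,associated
d008,J18.9,immediate
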