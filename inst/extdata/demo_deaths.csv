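record_id,year,age,sex,region,uc
d001,2019,83,female,north,I50.9
d002,2019,76,male,north,I21.0
d003,2019,68,female,south,C55
d004,2019,90,male,capital,R99
d005,2019,59,female,south,C54.9
d006,2019,47,male,north,X42
d007,2019,81,female,capital,J18.9
d008,2019,72,male,south,C34.1
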