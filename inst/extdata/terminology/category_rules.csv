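source_value,dimension,category
U01,level_of_care,emergency
U02,level_of_care,ward
U03,level_of_care,ward
U04,level_of_care,intensive_care
U05,level_of_care,intensive_care
U06,level_of_care,ward
U07,level_of_care,ward
U08,level_of_care,outpatient
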