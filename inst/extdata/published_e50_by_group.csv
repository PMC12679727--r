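cohort,group,sex,e50
CCDRFS,control,male,28.5
CCDRFS,control,female,33.1
CCDRFS,le1,male,28.6
CCDRFS,le1,female,33.2
CCDRFS,mid2to4,male,25.0
CCDRFS,mid2to4,female,29.6
CCDRFS,ge5,male,22.4
CCDRFS,ge5,female,27.0
NHANES,control,male,32.0
NHANES,control,female,35.2
NHANES,le1,male,33.9
NHANES,le1,female,36.8
NHANES,mid2to4,male,28.3
NHANES,mid2to4,female,31.8
NHANES,ge5,male,23.8
NHANES,ge5,female,27.6
UKB,control,male,32.6
UKB,control,female,35.0
UKB,le1,male,31.4
UKB,le1,female,33.9
UKB,mid2to4,male,27.9
UKB,mid2to4,female,30.7
UKB,ge5,male,25.1
UKB,ge5,female,28.0
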