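label,count,denominator,printed_pct
t2d_deaths_pooled,7650,46351,16.5
control_deaths_pooled,9349,91645,10.2
ccdrfs_t2d_deaths,2076,17423,11.9
ccdrfs_control_deaths,2974,34799,8.5
nhanes_t2d_deaths,1614,5752,28.1
nhanes_control_deaths,2342,10506,22.3
ukb_t2d_deaths,3960,23176,17.1
ukb_control_deaths,4033,46340,8.7
ukb_ge5_targets_met,1568,23176,6.8
ukb_all_lifestyle_targets,1429,23176,6.2
ukb_all_metabolic_targets,2318,23176,10.0
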