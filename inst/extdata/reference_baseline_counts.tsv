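# Reference cohort composition (report counts) used by scripts/acceptance.R
# section	category	count
total	reports	17953
sex	F	9711
sex	M	5752
age	under18	502
age	18to65	8681
age	over65	4963
age	missing	3807
reporter	healthcare	11756
reporter	non_healthcare	4668
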