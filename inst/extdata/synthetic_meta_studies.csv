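"study_id","population","drug","allele","case_carriers","case_total","control_carriers","control_total"
"study01","Han Chinese","OXC","HLA-A*24:02",17,51,14,94
"study02","Korean","CBZ","HLA-A*24:02",32,80,35,160
"study03","Thai","CBZ","HLA-A*24:02",17,45,16,90
"study04","Malaysian","LTG","HLA-A*24:02",24,60,41,150
"study05","Mexican","mixed","HLA-A*24:02",24,120,78,300
"study06","Han Chinese","mixed","HLA-A*24:02",36,132,109,483
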