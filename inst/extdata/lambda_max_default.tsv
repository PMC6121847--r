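# Peak absorbance (nm) of the seven cichlid cone opsins.
# Midas cichlid values; sws1 from Nile tilapia.
opsin	lambda_max_nm
sws1	360
sws2b	425
sws2a	456
rh2b	472
rh2ab	517
rh2aa	527
lws	560
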