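name	start	end	level
N-arm	1	1290	module
linker	1291	1774	module
AAA core	1775	3405	module
hinge	3406	3588	module
E3 module	3589	4926	module
CTD	4927	5148	module
IR3	2487	2538	subdomain
IR5	3063	3103	subdomain
E3-back	3589	3939	subdomain
E3-RING	3940	3999	subdomain
E3-shell	4000	4449	subdomain
E3-core	4450	4926	subdomain
CTD	4927	5148	subdomain
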