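origin_id,destination_id,count
17031,17043,1200
17043,17031,900
17031,36061,150
36061,17031,180
36061,36103,2100
36103,36061,1700
17043,36103,60
36103,17043,40
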