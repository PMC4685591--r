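name,file,n_tips,n_extant,crown_time,present
two_tip_extant,two_tip_extant.nwk,2,2,0,10
one_side_extinct,one_side_extinct.nwk,3,2,4,10
five_tip_mixed,five_tip_mixed.nwk,5,3,2,10
single_survivor,single_survivor.nwk,2,1,NA,8
crown_at_origin,crown_at_origin.nwk,3,2,0,10
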