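participant_id,days_earned,days_not_earned,total_gbp,tac_over,removal_over,data_overwritten
P4,0,15,0,15,0,0
P5,13,2,105,1,1,0
P6,12,3,95,1,2,0
P7,10,5,85,1,4,0
P10,12,3,90,1,2,0
P11,0,15,0,15,0,0
P16,2,13,10,0,6,7
P17,5,10,25,6,2,2
P18,9,6,55,0,6,0
P19,9,6,75,0,3,3
P21,13,2,110,0,2,0
P22,1,11,5,9,2,0
P25,3,12,15,2,10,0
P29,11,4,85,0,4,0
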