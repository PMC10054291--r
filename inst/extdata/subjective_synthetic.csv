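subject_id,eye,target_id,dx_pd,dy_pd
SYN01,LE,1,5,0
SYN01,LE,2,5,5
SYN01,LE,3,5,0
SYN01,LE,4,5,0
SYN01,LE,5,5,5
SYN01,LE,6,5,0
SYN01,LE,7,5,0
SYN01,LE,8,0,0
SYN01,LE,9,5,0
SYN01,LE,10,5,5
SYN01,LE,11,5,0
SYN01,LE,12,5,5
SYN01,LE,13,5,5
SYN01,LE,14,5,0
SYN01,LE,15,5,5
SYN01,LE,16,5,0
SYN01,LE,17,5,0
SYN01,RE,1,0,0
SYN01,RE,2,5,0
SYN01,RE,3,5,0
SYN01,RE,4,5,0
SYN01,RE,5,0,0
SYN01,RE,6,5,0
SYN01,RE,7,5,0
SYN01,RE,8,0,0
SYN01,RE,9,5,0
SYN01,RE,10,5,0
SYN01,RE,11,5,5
SYN01,RE,12,5,0
SYN01,RE,13,5,0
SYN01,RE,14,5,5
SYN01,RE,15,5,0
SYN01,RE,16,5,0
SYN01,RE,17,5,5
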