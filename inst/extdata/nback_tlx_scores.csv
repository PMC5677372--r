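subject,task,score
A,1-back,22
B,1-back,21
C,1-back,31
D,1-back,35
E,1-back,38
F,1-back,20
G,1-back,31
H,1-back,29
I,1-back,30
J,1-back,39
A,2-back,44
B,2-back,55
C,2-back,46
D,2-back,51
E,2-back,43
F,2-back,52
G,2-back,45
H,2-back,53
I,2-back,52
J,2-back,54
A,3-back,69
B,3-back,62
C,3-back,65
D,3-back,78
E,3-back,63
F,3-back,77
G,3-back,71
H,3-back,80
I,3-back,61
J,3-back,70
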