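token	valence
advantag	1.7
advers	-1.8
anxieti	-2
atrophi	-1.7
benefici	1.9
benefit	1.9
best	3.2
better	1.9
burden	-1.5
cancer	-2.7
care	1.5
damag	-2.2
death	-2.9
declin	-1.6
defici	-1.4
deficit	-1.5
degener	-1.9
degrad	-1.6
dementia	-2.1
depress	-2.5
diseas	-1.7
disord	-1.7
distress	-2
dysfunct	-1.8
effect	1.7
efficaci	1.3
enhanc	1.4
failur	-2.1
fatigu	-1.6
favor	1.8
frailti	-1.5
gain	1.4
good	1.9
harm	-2.2
health	1.1
healthi	1.7
impair	-1.8
improv	1.9
inflamm	-1.2
injuri	-1.8
longev	1.4
loss	-1.3
morbid	-1.9
mortal	-2.4
neg	-1.6
novel	1.2
optim	1.7
pain	-2.3
poor	-1.9
posit	1.8
prevent	1.2
promis	1.8
protect	1.4
qualiti	1.2
recoveri	1.4
rejuven	1.8
resili	1.6
restor	1.3
risk	-1.1
robust	1.3
safe	1.6
safeti	1.6
sever	-1.9
signific	1
strength	1.6
stress	-1.3
success	2.15
support	1.2
surviv	1.1
toxic	-2.2
train	0.9
vital	1.9
wellb	2.4
wors	-2.1
worst	-3.1
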