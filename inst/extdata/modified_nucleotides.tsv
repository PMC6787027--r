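code	name
S	mnm5s2U
{	mnm5U
)	cmnm5U
Q	queuosine
V	cmo5U
M	ac4C
}	2-lysidine
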