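token	orientation	annotation
good	0.5	Positive
great	0.9	Positive
calm	0.4	Positive
hopeful	0.7	Positive
bad	-0.5	Negative
awful	-0.9	Negative
tired	-0.4	Negative
worried	-0.6	Negative
table	0	Neutral
chair	0	Non-opinionated
hmm	0	Not-a-word
uh	0	Not-a-word
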