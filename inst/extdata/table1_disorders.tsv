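disorder	n
adhd	474
anxiety	320
asd	145
eating_disorder	2
intellectual_disability	13
language_disorder	5
learning_disorder	644
mood_disorder	96
motor_delay	4
ocd	80
tics	84
schizophrenia_spectrum	6
vcfs	1
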