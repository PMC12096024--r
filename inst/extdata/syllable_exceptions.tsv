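word	syllables
osteoarthritis	6
physiotherapy	6
osteoporosis	6
ibuprofen	4
naproxen	3
acetaminophen	6
hyaluronic	5
intraarticular	6
cardiovascular	6
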