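call_type	session	n
rumble	Bela Bela 2011	633
bark	Bela Bela 2011	1
noisy roar	Bela Bela 2011	18
tonal roar	Bela Bela 2011	0
mixed roar	Bela Bela 2011	0
trumpet	Bela Bela 2011	15
snort	Bela Bela 2011	3
grunt	Bela Bela 2011	0
unknown	Bela Bela 2011	11
rumble	Addo 2011	925
bark	Addo 2011	15
noisy roar	Addo 2011	41
tonal roar	Addo 2011	34
mixed roar	Addo 2011	56
trumpet	Addo 2011	166
snort	Addo 2011	103
grunt	Addo 2011	8
unknown	Addo 2011	22
rumble	Addo 2012	529
bark	Addo 2012	1
noisy roar	Addo 2012	19
tonal roar	Addo 2012	23
mixed roar	Addo 2012	20
trumpet	Addo 2012	137
snort	Addo 2012	87
grunt	Addo 2012	7
unknown	Addo 2012	6
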