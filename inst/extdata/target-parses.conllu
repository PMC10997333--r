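# sent_id = example_target
# interpretation = passive
1	The	_	_	_	_	2	_	_	_
2	dog	_	_	_	_	7	_	_	_
3	found	_	_	_	_	2	_	_	_
4	in	_	_	_	_	3	_	_	_
5	the	_	_	_	_	6	_	_	_
6	park	_	_	_	_	4	_	_	_
7	was	_	_	_	_	0	_	_	_
8	covered	_	_	_	_	7	_	_	_
9	in	_	_	_	_	8	_	_	_
10	mud	_	_	_	_	9	_	_	_

# sent_id = example_target
# interpretation = active
1	The	_	_	_	_	2	_	_	_
2	dog	_	_	_	_	3	_	_	_
3	found	_	_	_	_	0	_	_	_
4	in	_	_	_	_	3	_	_	_
5	the	_	_	_	_	6	_	_	_
6	park	_	_	_	_	4	_	_	_

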