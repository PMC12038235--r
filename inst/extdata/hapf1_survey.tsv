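region	examined	detected
Portugal	4	0
Spain	20	0
Tunisia	2	0
France	10	0
Europe	9	0
Switzerland	5	0
Germany	5	0
Austria	4	0
Italy	40	0
Croatia	5	0
Hungary	5	0
Bulgaria	5	0
Roumania	3	0
Turkey	5	0
Crimea	10	1
Israel	11	7
Iran	10	6
Caucasia	6	3
Armenia	10	8
Azerbaijan	10	6
Georgia	10	9
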