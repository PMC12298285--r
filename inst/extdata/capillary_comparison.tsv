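sample_id	reference_percent	device_percent	reported_relative_difference_percent
1	113	111.572	1.2
2	113	113.100	0.1
3	112	112.227	0.2
4	107	109.716	2.5
5	104	101.965	1.9
6	100	96.834	3.2
7	100	97.380	2.7
8	98	95.306	2.8
9	94	93.996	0.0
10	91	92.467	1.6
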