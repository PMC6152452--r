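year	success	failure
2008	11	23
2009	1	14
2010	16	11
2011	12	18
2012	17	15
2014	7	2
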