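chromosome	start	end	status	printed_length
chr2	10434969	10459620	hypo	24652
chr4	12757332	12759630	hypo	2299
chr4	12811931	12825347	hypo	13417
chr23	8953289	8962353	hypo	9065
chr23	8963500	8968835	hypo	5336
chr2	10501805	10506125	hyper	4321
chr2	10510445	10525439	hyper	14995
chr4	12739300	12755955	hyper	16565
chr4	12761969	12810081	hyper	48113
chr4	12825809	12992351	hyper	166543
chr4	13003454	13053416	hyper	49963
chr23	8948126	8953059	hyper	4934
chr23	8969236	8975202	hyper	5967
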