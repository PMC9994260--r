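contig	pos	strand	label
host	151	+	synthetic_target_01
host	421	-	synthetic_target_02
host	700	+	synthetic_target_03
phage	220	+	synthetic_target_04
phage	455	-	synthetic_target_05
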