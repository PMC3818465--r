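@UTF8
@Begin
@Languages:	eng
@Participants:	CHI Mia Target_Child , MOT Ann Mother
@ID:	eng|synthetic|CHI|1;02.|female|||Target_Child|||
@ID:	eng|synthetic|MOT|29;00.|female|||Mother|||
*CHI:	baba .
%pho:	baba
*CHI:	dada .
%pho:	dada
*MOT:	good baby .
%pho:	bebi
*CHI:	pata .
%pho:	pʰata
*CHI:	kaka .
%pho:	kaka
@End
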