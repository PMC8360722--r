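# Character feature table: char<TAB>stroke<TAB>structure<TAB>pinyin
# Codes for 太 and 阳 follow the published SSP2VEC code book; every other
# entry is a SYNTHETIC example shaped like real entries (digit stroke code,
# 2-digit structure class, pinyin + uppercase tone letter).
太	1344	96	taiD
阳	522511	66	yangB
他	32525	13	taA
怹	325254544	61	tanA
伤	313525	13	shangA
寒	444512341124	61	hanB
初	4523453	13	chuA
感	13125114544	61	ganC
始	53154251	13	shiC
于	112	90	yuB
故	122513134	13	guD
以	5434	13	yiC
发	53544	95	faA
汗	441112	13	hanD
为	4354	94	weiB
先	312135	61	xianA
甘	12211	90	ganA
草	1222511112	61	caoC
桂	1234121121	13	guiD
枝	12341254	13	zhiA
麻	41312341234	80	maB
黄	122125121	61	huangB
附	5232124	13	fuD
子	521	90	ziC
细	55425121	13	xiD
辛	4143112	61	xinA
杏	1234251	61	xingD
仁	3211	13	renB
桔	1234121251	13	jieB
梗	12341251134	13	gengC
白	32511	90	baiB
术	12344	90	shuD
党	2434525135	61	dangC
参	5434333	61	shenA
茯	122321344	61	fuB
苓	12234454	61	lingB
麦	113544	61	maiD
冬	35444	61	dongA
心	4544	90	xinA
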