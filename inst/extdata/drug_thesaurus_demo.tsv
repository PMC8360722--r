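# Drug thesaurus: standard_name[<TAB>alias1,alias2,...]
甘草	国老
生姜
芍药
桂枝
大枣
麻黄
附子
细辛
杏仁
桔梗
白术
党参
茯苓
红花
白芍
川芎
桃仁
当归
熟地黄
干姜
半夏
人参
大黄
板蓝根
蒲公英
金银花
鱼腥草
连翘
野菊花
紫花地丁
败酱草
猪苓
陈皮
青皮
麦冬
玉竹
沙参
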