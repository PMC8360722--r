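# Traditional -> simplified mapping (per-character), partial demo table.
醫	医
藥	药
湯	汤
參	参
黃	黄
當	当
歸	归
術	术
證	证
風	风
熱	热
瀉	泻
陽	阳
陰	阴
傷	伤
經	经
臟	脏
腎	肾
膽	胆
氣	气
來	来
後	后
發	发
麥	麦
門	门
問	问
連	连
蓮	莲
龍	龙
棗	枣
薑	姜
蟲	虫
濕	湿
滿	满
嘔	呕
頭	头
體	体
裏	里
脈	脉
細	细
數	数
實	实
虛	虚
無	无
為	为
於	于
與	与
則	则
見	见
飲	饮
調	调
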