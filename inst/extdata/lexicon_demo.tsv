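# Segmentation lexicon (demo)
伤寒
初感
始于
太阳
故以
发汗
为先
甘草
桂枝
麻黄
附子
细辛
杏仁
桔梗
白术
党参
茯苓
麦冬
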